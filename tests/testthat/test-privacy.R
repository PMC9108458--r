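test_that("Gaussian-mechanism Renyi divergence matches numerical quadrature", {
  for (alpha in c(1.5, 2, 4, 8, 16)) {
    for (sigma in c(0.5, 1, 2)) {
      expect_equal(rdp_gaussian(alpha, sigma),
                   renyi_quadrature_gaussian(alpha, sigma),
                   tolerance = 1e-6)
    }
  }
  # KL limit as alpha -> 1+: unit-shifted Gaussians have KL = 1/(2 sigma^2)
  expect_equal(rdp_gaussian(1 + 1e-9, 1), 0.5, tolerance = 1e-6)
  # infinite noise destroys information
  expect_lt(rdp_gaussian(4, 1e6), 1e-10)
  expect_error(rdp_gaussian(1, 1), "order")
  expect_error(rdp_gaussian(2, 0), "sigma")
})

test_that("subsampled Gaussian bound is exact at integer orders and amplifies", {
  # q = 1 reduces to the full mechanism; q = 0 leaks nothing
  expect_equal(rdp_subsampled_gaussian(2, 1, 1), 1.0)
  expect_equal(rdp_subsampled_gaussian(2, 1, 0), 0)
  # binomial expansion against direct quadrature of the mixture divergence
  for (alpha in c(2, 3, 5, 8)) {
    for (q in c(0.01, 0.1, 0.5)) {
      expect_equal(rdp_subsampled_gaussian(alpha, 1, q),
                   renyi_quadrature_subsampled(alpha, 1, q),
                   tolerance = 1e-9)
    }
  }
  # subsampling can only improve privacy
  for (alpha in c(2, 4, 16, 64)) {
    for (q in c(0.001, 0.1, 0.9, 1)) {
      expect_lte(rdp_subsampled_gaussian(alpha, 0.8, q),
                 rdp_gaussian(alpha, 0.8) + 1e-12)
    }
  }
  # interpolated non-integer order sits between its integer brackets
  mid <- rdp_subsampled_gaussian(2.5, 1, 0.1)
  expect_gte(mid, rdp_subsampled_gaussian(2, 1, 0.1))
  expect_lte(mid, rdp_subsampled_gaussian(3, 1, 0.1))
  expect_error(rdp_subsampled_gaussian(1.5, 1, 0.1), "order")
})

test_that("ledger composition is exactly additive", {
  led <- rdp_ledger(c(2, 4))
  expect_identical(compose(led, c(1, 2), 0L), led)   # zero steps: unchanged
  a <- compose(compose(led, c(1, 2), 1L), c(1, 2), 1L)
  b <- compose(led, c(1, 2), 2L)
  expect_equal(a$eps_rdp, b$eps_rdp)
  expect_equal(a$steps, b$steps)
  led100 <- compose(rdp_ledger(2), rdp_gaussian(2, 1), 100L)
  expect_equal(led100$eps_rdp, 100)
  expect_error(compose(led, c(1, 2, 3), 1L), "order grid")
})

test_that("RDP to (epsilon, delta) conversion matches hand evaluation", {
  led <- compose(rdp_ledger(2), 1, 1L)
  rep <- rdp_to_dp(led, 0.01)
  expect_equal(rep$epsilon, 1 + log(1 / 2) - (log(0.01) + log(2)) / 1,
               tolerance = 1e-12)
  expect_equal(rep$epsilon, 4.2189, tolerance = 1e-3)
  expect_equal(rep$best_order, 2)
  # larger delta gives a smaller converted epsilon
  expect_lt(rdp_to_dp(led, 0.1)$epsilon, rep$epsilon)
  # minimum over a 2-order grid equals the smaller single-order conversion
  led2 <- compose(rdp_ledger(c(2, 8)), c(1, 3), 1L)
  one <- rdp_to_dp(compose(rdp_ledger(2), 1, 1L), 0.01)$epsilon
  two <- rdp_to_dp(compose(rdp_ledger(8), 3, 1L), 0.01)$epsilon
  expect_equal(rdp_to_dp(led2, 0.01)$epsilon, min(one, two))
})

test_that("converted epsilon is monotone in noise and steps", {
  q <- 0.05
  eps_of <- function(sigma, steps) {
    account_dp(sigma, q, delta = 1e-5, steps = steps)$epsilon
  }
  sig_grid <- c(0.6, 0.8, 1, 1.5, 2)
  vals <- vapply(sig_grid, eps_of, numeric(1), steps = 500)
  expect_true(all(diff(vals) < 0))           # non-increasing in sigma
  step_grid <- c(10, 100, 500, 2000)
  vals2 <- vapply(step_grid, function(s) eps_of(1, s), numeric(1))
  expect_true(all(diff(vals2) > 0))          # non-decreasing in steps
  # non-private arm reports infinity
  expect_identical(account_dp(0, q, 1e-5, 100)$epsilon, Inf)
})

test_that("clip_and_noise clips per-sample norms and reproduces hand cases", {
  # below-clip gradient passes through untouched at sigma = 0
  r <- clip_and_noise(matrix(c(0.3, 0.4), 1), clip_norm = 1, sigma = 0)
  expect_equal(r$grad, c(0.3, 0.4))
  # (3, 4) clipped to unit norm
  r <- clip_and_noise(matrix(c(3, 4), 1), clip_norm = 1, sigma = 0)
  expect_equal(r$grad, c(0.6, 0.8))
  # every contributing gradient respects the norm bound after clipping
  set.seed(5)
  g <- matrix(rnorm(50 * 8, sd = 3), 50, 8)
  r <- clip_and_noise(g, clip_norm = 1.5, sigma = 0)
  clipped <- g * r$clip_scale
  expect_true(all(sqrt(rowSums(clipped^2)) <= 1.5 + 1e-9))
  expect_error(clip_and_noise(matrix(numeric(0), 0, 2), 1, 0), "non-empty")
})

test_that("noise variance matches (sigma C / B)^2 empirically", {
  set.seed(17)
  sigma <- 0.8; C <- 2; B <- 4
  g <- matrix(0, B, 3)                      # zero gradients isolate the noise
  draws <- replicate(10000, clip_and_noise(g, C, sigma)$grad[1])
  expect_equal(stats::var(draws), (sigma * C / B)^2, tolerance = 0.05)
})

test_that("ledger JSON serialization round-trips bit-exactly", {
  orders <- default_rdp_orders(fine = FALSE)
  led <- compose(rdp_ledger(orders),
                 rdp_subsampled_gaussian(orders, 0.73, 0.013), 377L)
  path <- tempfile(fileext = ".json")
  write_ledger(led, path)
  back <- read_ledger(path)
  expect_identical(back$orders, led$orders)
  expect_identical(back$eps_rdp, led$eps_rdp)
  expect_identical(back$steps, led$steps)
})
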