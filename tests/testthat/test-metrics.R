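test_that("dsc reproduces hand counts and its conventions", {
  m <- function(...) matrix(c(...), 2)
  expect_equal(dsc(m(1, 1, 0, 0), m(1, 1, 0, 0)), 1)     # identical, non-empty
  expect_equal(dsc(m(1, 0, 0, 0), m(0, 0, 0, 1)), 0)     # disjoint
  # TP=2, FP=1, FN=1 -> 4/6
  pred <- matrix(c(1, 1, 1, 0, 0, 0), 2, 3)
  gt <- matrix(c(1, 1, 0, 1, 0, 0), 2, 3)
  expect_equal(dsc(pred, gt), 2 / 3)
  expect_equal(dsc(pred, gt), dsc(gt, pred))             # symmetric
  z <- matrix(0, 2, 2)
  expect_equal(dsc(z, z), 1)                             # both empty
  expect_equal(dsc(z, m(1, 0, 0, 0)), 0)                 # one empty
  expect_error(dsc(z, matrix(0, 3, 3)), "shape")
})

test_that("bahd reproduces hand evaluations of the printed formula", {
  g <- matrix(0, 8, 8); s <- matrix(0, 8, 8)
  g[1, 1] <- 1; s[1, 1] <- 1
  expect_equal(bahd(g, s), 0)                            # G == S
  s[1, 1] <- 0; s[4, 5] <- 1                             # 3-4-5 triangle
  expect_equal(bahd(g, s), 5)
  # |G| = 2, |S| = 1: ((0 + 1)/2 + 0/2)/2 = 0.25
  g2 <- matrix(0, 4, 4); s2 <- matrix(0, 4, 4)
  g2[1, 1] <- 1; g2[2, 1] <- 1; s2[1, 1] <- 1
  expect_equal(bahd(g2, s2), 0.25)
  # both directed sums divide by N_G, so swapping arguments changes the
  # value whenever |G| != |S| -- this pins the printed formula down
  expect_false(isTRUE(all.equal(bahd(g2, s2), bahd(s2, g2))))
  # false positives far from a small ground truth are punished heavily
  many_fp <- g2; many_fp[, 3:4] <- 1
  expect_gt(bahd(g2, many_fp), bahd(g2, g2 * 0 + diag(4)))
  expect_error(bahd(matrix(0, 2, 2), s2[1:2, 1:2]), "empty")
  # physical spacing scales distances
  expect_equal(bahd(g, s, spacing = c(2, 2)), 10)
})

test_that("bahd agrees with the brute-force distance matrix on random masks", {
  set.seed(41)
  for (i in 1:200) {
    nr <- sample(2:6, 1); nc <- sample(2:6, 1)
    gt <- random_mask(nr, nc, runif(1, 0.15, 0.6))
    pr <- random_mask(nr, nc, runif(1, 0.15, 0.6))
    expect_equal(bahd(gt, pr), bahd_bruteforce(gt, pr), tolerance = 1e-12)
  }
})

test_that("frechet distance matches closed forms and is rotation-invariant", {
  one_d <- function(mu, v) list(mu = mu, cov = matrix(v, 1, 1))
  a <- feature_stats(matrix(rnorm(60), 30, 2))
  expect_equal(frechet_distance(a, a), 0, tolerance = 1e-10)
  # 1-D closed form: 9 + (1 + 4 - 2 sqrt(4)) = 10
  expect_equal(frechet_distance(one_d(0, 1), one_d(3, 4)), 10, tolerance = 1e-8)
  # commuting diagonal covariances: sum (sqrt(v1) - sqrt(v2))^2 + |dmu|^2
  d1 <- list(mu = c(1, -2, 0), cov = diag(c(1, 4, 9)))
  d2 <- list(mu = c(0, 0, 1), cov = diag(c(4, 1, 1)))
  closed <- sum((sqrt(c(1, 4, 9)) - sqrt(c(4, 1, 1)))^2) + sum((d1$mu - d2$mu)^2)
  expect_equal(frechet_distance(d1, d2), closed, tolerance = 1e-8)
  # simultaneous rotation of both feature sets leaves the distance unchanged
  set.seed(7)
  xa <- matrix(rnorm(300), 100, 3)
  xb <- matrix(rnorm(300, sd = 1.4) + 0.5, 100, 3)
  base <- frechet_distance(feature_stats(xa), feature_stats(xb))
  for (k in 1:3) {
    q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    rot <- frechet_distance(feature_stats(xa %*% q), feature_stats(xb %*% q))
    expect_equal(rot, base, tolerance = 1e-8)
  }
  expect_gte(base, 0)
})

test_that("extract_features computes hand-checkable moments", {
  imgs <- list(matrix(0.2, 4, 4), matrix(0.5, 4, 4), matrix(0.8, 4, 4))
  ex <- function(im) c(mean(im), max(im))
  fs <- extract_features(imgs, ex)
  expect_equal(fs$mu, c(0.5, 0.5))
  expect_equal(fs$cov, stats::cov(cbind(c(0.2, 0.5, 0.8), c(0.2, 0.5, 0.8))))
  # permutation invariance
  fs2 <- extract_features(imgs[c(3, 1, 2)], ex)
  expect_equal(fs2$mu, fs$mu)
  expect_equal(fs2$cov, fs$cov)
  # identical images give zero covariance
  fs3 <- extract_features(list(matrix(0.3, 4, 4), matrix(0.3, 4, 4)), ex)
  expect_equal(max(abs(fs3$cov)), 0)
  expect_error(extract_features(list(matrix(0, 4, 4)), ex), "at least 2")
})

test_that("ssim matches hand simplifications and sign analysis", {
  set.seed(3)
  x <- matrix(runif(64), 8)
  expect_equal(ssim(x, x), 1)
  # constant images: contrast/structure term cancels, luminance term remains
  a <- 0.3; b <- 0.7; c1 <- (0.01 * 1)^2
  expect_equal(ssim(matrix(a, 5, 5), matrix(b, 5, 5)),
               (2 * a * b + c1) / (a^2 + b^2 + c1), tolerance = 1e-12)
  # anti-correlated centered images score negative
  x2 <- matrix(c(0.9, 0.1, 0.1, 0.9), 2)
  y2 <- matrix(c(0.1, 0.9, 0.9, 0.1), 2)
  expect_lt(ssim(x2, y2), 0)
  # ssim(x, x + eps) -> 1 monotonically as the perturbation shrinks
  set.seed(9)
  eps <- matrix(rnorm(64), 8)
  vals <- vapply(c(0.2, 0.05, 0.01, 0.001),
                 function(s) ssim(x, pmin(pmax(x + s * eps, 0), 1)), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_gt(vals[4], 0.999)
  # sliding-window mode stays 1 on identical inputs and below it under noise
  expect_equal(ssim(x, x, window = 4), 1)
  expect_lt(ssim(x, pmin(pmax(x + 0.1 * eps, 0), 1), window = 4), 1)
  expect_error(ssim(x, matrix(0, 4, 4)), "shape")
})

test_that("mean pairwise SSIM matches the exhaustive loop and flags collapse", {
  set.seed(11)
  imgs <- lapply(1:3, function(i) matrix(runif(36), 6))
  got <- mean_pairwise_ssim(imgs)
  manual <- mean(c(ssim(imgs[[1]], imgs[[2]]), ssim(imgs[[1]], imgs[[3]]),
                   ssim(imgs[[2]], imgs[[3]])))
  expect_equal(got$mean_ssim, manual)
  expect_equal(got$n_pairs_scored, 3L)
  # a collapsed collection scores exactly 1
  same <- lapply(1:4, function(i) imgs[[1]])
  expect_equal(mean_pairwise_ssim(same)$mean_ssim, 1)
  expect_error(mean_pairwise_ssim(imgs[1]), "at least 2")
  # subsampling path is seeded and bounded
  many <- lapply(1:20, function(i) matrix(runif(16), 4))
  r1 <- mean_pairwise_ssim(many, max_pairs = 50L, seed = 4)
  r2 <- mean_pairwise_ssim(many, max_pairs = 50L, seed = 4)
  expect_equal(r1$mean_ssim, r2$mean_ssim)
  expect_equal(r1$n_pairs_scored, 50L)
})
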