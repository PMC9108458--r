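test_that("network builders respect the shape contracts", {
  cfg <- micro_gan_config()
  set.seed(2)
  gen <- build_generator(cfg)
  z <- matrix(0, cfg$latent_dim, 1)
  out1 <- dpvessel:::net_forward(gen, z, keep_cache = FALSE)$out
  expect_identical(dim(out1), c(16L, 16L, 2L, 1L))        # P = base * 2^stages
  out2 <- dpvessel:::net_forward(gen, z, keep_cache = FALSE)$out
  expect_identical(out1, out2)                            # deterministic map
  # paper-scale shape contract: 2 x 96 x 96
  cfg96 <- gan_config("paper")
  gen96 <- build_generator(cfg96)
  o96 <- dpvessel:::net_forward(gen96, matrix(0, 128, 1), keep_cache = FALSE)$out
  expect_identical(dim(o96), c(96L, 96L, 2L, 1L))
  # desk-scale shape arithmetic: P = 32 with 5 stages (base 1)
  cfg32 <- gan_config("desk", patch_size = 32, n_stages = 5)
  o32 <- dpvessel:::net_forward(build_generator(cfg32), matrix(0, 128, 1),
                                keep_cache = FALSE)$out
  expect_identical(dim(o32)[1:2], c(32L, 32L))
  expect_error(gan_config("desk", patch_size = 48, n_stages = 5), "divisible")

  cri <- build_critic(cfg)
  x <- array(rnorm(16 * 16 * 2 * 7), c(16, 16, 2, 7))
  s <- dpvessel:::net_forward(cri, x, keep_cache = FALSE)$out
  expect_identical(dim(s), c(1L, 7L))                     # batch of N -> N scores
  s2 <- dpvessel:::net_forward(cri, x, keep_cache = FALSE)$out
  expect_identical(s, s2)                                 # identical inputs
})

test_that("critic gradients are correct and per-sample slicing is exact", {
  cfg <- micro_gan_config()
  set.seed(3)
  cri <- build_critic(cfg)
  x <- array(rnorm(16 * 16 * 2 * 4), c(16, 16, 2, 4))
  # finite-difference check of the batched parameter gradient of sum(D(x))
  fw <- dpvessel:::net_forward(cri, x)
  bw <- dpvessel:::net_backward(cri, fw$caches, matrix(1, 1, 4))
  g <- dpvessel:::grads_flatten(cri, bw$grads)
  theta <- dpvessel:::net_flatten_params(cri)
  set.seed(4)
  idx <- sample(length(theta), 25)
  h <- 1e-5
  for (j in idx) {
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    fp <- sum(dpvessel:::net_forward(dpvessel:::net_set_params(cri, tp), x,
                                     keep_cache = FALSE)$out)
    fm <- sum(dpvessel:::net_forward(dpvessel:::net_set_params(cri, tm), x,
                                     keep_cache = FALSE)$out)
    expect_equal(g[j], (fp - fm) / (2 * h), tolerance = 1e-4)
  }
  # per-sample gradients equal the one-sample-at-a-time recomputation
  fast <- dpvessel:::critic_per_sample_grads(cri, x)
  for (i in 1:4) {
    fwi <- dpvessel:::net_forward(cri, x[, , , i, drop = FALSE])
    bwi <- dpvessel:::net_backward(cri, fwi$caches, matrix(1, 1, 1))
    expect_equal(fast$grads[i, ], dpvessel:::grads_flatten(cri, bwi$grads),
                 tolerance = 1e-12)
  }
  # and their sum is the batched gradient
  expect_equal(colSums(fast$grads), g, tolerance = 1e-10)
})

test_that("generator gradients pass a finite-difference check", {
  cfg <- micro_gan_config()
  set.seed(6)
  gen <- build_generator(cfg)
  z <- matrix(rnorm(cfg$latent_dim * 2), cfg$latent_dim, 2)
  loss_of <- function(net) {
    out <- dpvessel:::gen_head_forward(
      dpvessel:::net_forward(net, z, keep_cache = FALSE)$out)
    sum(out^2)
  }
  fw <- dpvessel:::net_forward(gen, z)
  head_out <- dpvessel:::gen_head_forward(fw$out)
  draw <- dpvessel:::gen_head_backward(fw$out, head_out, 2 * head_out)
  g <- dpvessel:::grads_flatten(gen, dpvessel:::net_backward(gen, fw$caches, draw)$grads)
  theta <- dpvessel:::net_flatten_params(gen)
  set.seed(7)
  for (j in sample(length(theta), 20)) {
    h <- 1e-5
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    num <- (loss_of(dpvessel:::net_set_params(gen, tp)) -
              loss_of(dpvessel:::net_set_params(gen, tm))) / (2 * h)
    expect_equal(g[j], num, tolerance = 1e-4)
  }
})

test_that("wgan losses reproduce hand evaluations", {
  l <- wgan_losses(0.9, 0.3)
  expect_equal(l$loss_G, -0.3)
  expect_equal(l$loss_D, -0.6)
  s <- rnorm(5)
  expect_equal(wgan_losses(s, s)$loss_D, 0)
  expect_equal(wgan_losses(rnorm(5), s)$loss_G, -mean(s))
})

test_that("a noiseless unclipped critic step matches a hand-rolled WGAN step", {
  # two-parameter critic D(x) = w x + b on scalar "patches": one RMSprop
  # step on loss_D computed by hand must match the engine's arithmetic
  w <- 0.3; b <- -0.1; lr <- 0.01
  x_real <- c(1, 2); x_gen <- c(0.5, -1)
  # d loss_D / dw = mean(x_gen) - mean(x_real); d/db = 0
  gw <- mean(x_gen) - mean(x_real)
  gb <- 0
  v <- (1 - 0.99) * c(gw, gb)^2
  hand <- c(w, b) - lr * c(gw, gb) / (sqrt(v) + 1e-8)
  st <- dpvessel:::rmsprop_state(2)
  per_sample <- cbind(x_gen - x_real, 0)      # d(D(xg_i) - D(xr_i))/d(w, b)
  agg <- clip_and_noise(per_sample, clip_norm = 1e9, sigma = 0)
  upd <- dpvessel:::rmsprop_step(c(w, b), agg$grad, st, lr)
  expect_equal(upd$theta, hand, tolerance = 1e-12)
})

test_that("training is reproducible, clips critic weights and fills the ledger", {
  ps <- small_patches()
  cfg <- micro_gan_config(sigma = 0, seed = 21, epochs = 2)
  s1 <- train_gan(cfg, ps)
  s2 <- train_gan(cfg, ps)
  expect_identical(dpvessel:::net_flatten_params(s1$generator),
                   dpvessel:::net_flatten_params(s2$generator))
  expect_identical(dpvessel:::net_flatten_params(s1$critic),
                   dpvessel:::net_flatten_params(s2$critic))
  # critic weights clipped to +/- 0.01 after every step
  expect_lte(dpvessel:::net_max_abs_weight(s1$critic), 0.01 + 1e-12)
  # non-private arm: ledger untouched, epsilon infinite
  expect_identical(s1$ledger$steps, 0L)
  expect_identical(s1$dp_report$epsilon, Inf)
  # epoch convention: ceiling(180/32) = 6 critic batches per epoch
  expect_equal(nrow(s1$losses), 2 * 6)
  expect_true(all(is.finite(s1$losses$loss_D)))

  # private arm: one composition per critic update, none for the generator
  cfgp <- micro_gan_config(sigma = 1, seed = 22, epochs = 2)
  sp <- train_gan(cfgp, ps)
  expect_identical(sp$ledger$steps, 12L)
  expect_equal(sp$dp_report$epsilon,
               account_dp(1, 32 / 180, 1 / 180, steps = 12)$epsilon)
})

test_that("synthesize produces binary labels, unit-range images, deterministically", {
  ps <- small_patches()
  st <- fixture("tiny_gan", function() {
    train_gan(micro_gan_config(sigma = 0, seed = 31, epochs = 3), small_patches())
  })
  a <- synthesize(st, n = 40, seed = 9)
  b <- synthesize(st, n = 40, seed = 9)
  expect_identical(a$patches[[17]]$image, b$patches[[17]]$image)
  expect_length(a$patches, 40L)
  expect_true(all(vapply(a$patches, function(p)
    all(p$label %in% c(0L, 1L)) && all(p$image >= 0) && all(p$image <= 1),
    logical(1))))
  expect_true(all(a$manifest$mode == "generated"))
  expect_error(synthesize(st, n = 0), "positive")
})
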