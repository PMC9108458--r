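# Shared fixtures, built once per test run. Sizes are chosen so the whole
# suite stays CPU-friendly; the methods vignette documents the scales.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}

small_volume <- function(seed = 1, n_vessels = 5) {
  fixture(paste0("vol", seed, "_", n_vessels), function() {
    generate_volume(seed = seed, shape = c(48, 48, 32), n_vessels = n_vessels)
  })
}

small_patches <- function() {
  fixture("patches16", function() {
    bind_patch_sets(lapply(1:3, function(i) {
      extract_patches(small_volume(i), 30, 30, patch_size = 16, seed = 100 + i)
    }))
  })
}

micro_gan_config <- function(sigma = 0, seed = 11, epochs = 5, n_data = 180) {
  gan_config("desk", patch_size = 16, n_stages = 3, base_channels = 8,
             epochs = epochs, lr = 5e-4,
             privacy = privacy_spec(max(sigma, 0), clip_norm = 1,
                                    sample_rate = 32 / n_data,
                                    delta = 1 / n_data),
             seed = seed)
}

# independent Renyi-divergence quadrature between N(1, s^2) and N(0, s^2);
# the integrand is evaluated in log space to dodge 0^a * 0^(1-a) = NaN
renyi_quadrature_gaussian <- function(alpha, sigma) {
  g <- function(x) alpha * dnorm(x, 1, sigma, log = TRUE) +
    (1 - alpha) * dnorm(x, 0, sigma, log = TRUE)
  # shift by the integrand's log-maximum so exp() cannot overflow
  x_star <- stats::optimize(g, c(-50, 50), maximum = TRUE)$maximum
  g_max <- g(x_star)
  val <- stats::integrate(function(x) exp(g(x) - g_max),
                          x_star - 15 * sigma, x_star + 15 * sigma,
                          rel.tol = 1e-12)$value
  (g_max + log(val)) / (alpha - 1)
}

# quadrature for the subsampled mechanism: mixture vs base Gaussian
renyi_quadrature_subsampled <- function(alpha, sigma, q) {
  f <- function(x) {
    lmix <- log((1 - q) * dnorm(x, 0, sigma) + q * dnorm(x, 1, sigma))
    exp(alpha * lmix + (1 - alpha) * dnorm(x, 0, sigma, log = TRUE))
  }
  log(stats::integrate(f, -20 * sigma, 20 * sigma, rel.tol = 1e-12)$value) /
    (alpha - 1)
}

# brute-force balanced average Hausdorff distance from a full distance matrix
bahd_bruteforce <- function(gt, pred) {
  G <- which(gt != 0, arr.ind = TRUE)
  S <- which(pred != 0, arr.ind = TRUE)
  dmat <- matrix(0, nrow(G), nrow(S))
  for (i in seq_len(nrow(G))) for (j in seq_len(nrow(S))) {
    dmat[i, j] <- sqrt(sum((G[i, ] - S[j, ])^2))
  }
  ng <- nrow(G)
  (sum(apply(dmat, 1, min)) / ng + sum(apply(dmat, 2, min)) / ng) / 2
}

overfit_unet_model <- function() {
  fixture("overfit_unet", function() {
    ps <- small_patches()
    sub <- ps
    sub$patches <- ps$patches[1:40]
    sub$manifest <- ps$manifest[1:40, ]
    train_unet(sub, seg_config(lr = 1e-3, epochs = 60, seed = 5))
  })
}

random_mask <- function(nr, nc, p = 0.3, nonempty = TRUE) {
  repeat {
    m <- matrix(rbinom(nr * nc, 1, p), nr, nc)
    if (!nonempty || sum(m) > 0) return(m)
  }
}
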