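#' Dice similarity coefficient of two binary masks
#'
#' \eqn{DSC = 2TP / (2TP + FP + FN)}. By the continuity convention adopted
#' here, two empty masks score 1 (perfect agreement on "nothing to segment")
#' and exactly one empty mask scores 0; the raw formula is 0/0 in the first
#' case.
#'
#' @param pred,gt Binary arrays of identical shape (any dimensionality);
#'   values coerced with `!= 0`.
#' @return Scalar in \eqn{[0, 1]}.
#' @examples
#' dsc(matrix(c(1, 1, 0, 0), 2), matrix(c(1, 0, 1, 0), 2))
#' @export
dsc <- function(pred, gt) {
  if (!identical(dim2(pred), dim2(gt))) {
    stop("pred and gt must have identical shape")
  }
  p <- pred != 0
  g <- gt != 0
  tp <- sum(p & g)
  fp <- sum(p & !g)
  fn <- sum(!p & g)
  if (tp + fp + fn == 0) return(1)
  2 * tp / (2 * tp + fp + fn)
}

# dim() that treats a plain vector as 1-D
dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Confusion counts between two binary masks
#'
#' @param pred,gt Binary arrays of identical shape.
#' @return A one-row tibble with columns `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(pred, gt) {
  if (!identical(dim2(pred), dim2(gt))) stop("pred and gt must have identical shape")
  p <- pred != 0
  g <- gt != 0
  tibble::tibble(tp = sum(p & g), fp = sum(p & !g),
                 fn = sum(!p & g), tn = sum(!p & !g))
}

# voxel coordinates (rows) of non-zero entries, scaled by spacing if given
mask_coords <- function(mask, spacing = NULL) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (is.null(dim(mask))) idx <- matrix(idx, ncol = 1L)
  co <- matrix(as.numeric(idx), nrow = nrow(idx))
  if (!is.null(spacing)) {
    if (length(spacing) != ncol(co)) stop("spacing length must match mask dimensionality")
    co <- sweep(co, 2L, as.numeric(spacing), `*`)
  }
  co
}

# for every row of a, Euclidean distance to the nearest row of b; both
# sides are chunked with a running minimum so memory stays O(chunk^2)
# regardless of mask size
nn_dist <- function(a, b, chunk = 1024L) {
  bsq <- rowSums(b^2)
  out <- numeric(nrow(a))
  for (s in seq(1L, nrow(a), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(a))
    ac <- a[s:e, , drop = FALSE]
    asq <- rowSums(ac^2)
    best <- rep(Inf, nrow(ac))
    for (sb in seq(1L, nrow(b), by = chunk)) {
      eb <- min(sb + chunk - 1L, nrow(b))
      bc <- b[sb:eb, , drop = FALSE]
      d2 <- outer(asq, bsq[sb:eb], `+`) - 2 * tcrossprod(ac, bc)
      best <- pmin(best, apply(d2, 1L, min))
    }
    out[s:e] <- sqrt(pmax(best, 0))
  }
  out
}

#' Balanced average Hausdorff distance
#'
#' The average of the two directed mean nearest-neighbour distances between
#' the ground-truth voxel set \eqn{G} and the predicted voxel set \eqn{S},
#' with \emph{both} directed sums normalized by the ground-truth voxel count
#' \eqn{N_G}:
#' \deqn{bAHD = \frac{1}{2}\left(\frac{1}{N_G}\sum_{g\in G}\min_{s\in S}
#'   d(g,s) + \frac{1}{N_G}\sum_{s\in S}\min_{g\in G} d(s,g)\right).}
#' Normalizing the second sum by \eqn{N_G} rather than \eqn{|S|} makes the
#' metric penalize false positives heavily when \eqn{|S| \gg N_G}, and makes
#' it asymmetric in its arguments whenever \eqn{|G| \ne |S|} — this is
#' deliberate and distinguishes it from the conventional average Hausdorff
#' distance.
#'
#' @param gt Ground-truth binary array (defines \eqn{G} and \eqn{N_G}).
#' @param pred Predicted binary array of the same shape (defines \eqn{S}).
#' @param spacing Optional per-axis voxel size; distances are then in the
#'   same physical units, otherwise in voxels.
#' @return Non-negative scalar; errors if either mask is empty (the metric
#'   is undefined there).
#' @export
bahd <- function(gt, pred, spacing = NULL) {
  if (!identical(dim2(pred), dim2(gt))) stop("pred and gt must have identical shape")
  G <- mask_coords(gt, spacing)
  S <- mask_coords(pred, spacing)
  if (nrow(G) == 0L) stop("ground-truth mask is empty; bAHD is undefined")
  if (nrow(S) == 0L) stop("predicted mask is empty; bAHD is undefined")
  ng <- nrow(G)
  (sum(nn_dist(G, S)) / ng + sum(nn_dist(S, G)) / ng) / 2
}

#' Sufficient statistics of a feature embedding
#'
#' Mean vector and covariance matrix of a set of fixed-length feature
#' vectors — the inputs to the Frechet distance.
#'
#' @param features Numeric matrix, rows = observations, columns = features.
#' @return An object of class `feature_stats`: list with `mu`, `cov`, `n`.
#' @export
feature_stats <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 2L) stop("need at least 2 observations for a covariance")
  if (any(!is.finite(features))) stop("features must be finite")
  structure(
    list(mu = colMeans(features), cov = stats::cov(features), n = nrow(features)),
    class = "feature_stats"
  )
}

# principal square root of a symmetric PSD matrix via eigendecomposition;
# small negative eigenvalues from round-off are clamped to zero
sym_sqrtm <- function(m, tol = 1e-8) {
  es <- eigen((m + t(m)) / 2, symmetric = TRUE)
  lam <- es$values
  if (any(lam < -tol * max(abs(lam), 1))) {
    stop("matrix is not positive semi-definite within tolerance")
  }
  lam <- pmax(lam, 0)
  es$vectors %*% (sqrt(lam) * t(es$vectors))
}

#' Frechet distance between two feature Gaussians
#'
#' \deqn{d^2 = \|\mu_a - \mu_b\|^2 +
#'   \mathrm{Tr}\left(\Sigma_a + \Sigma_b - 2(\Sigma_a\Sigma_b)^{1/2}\right)}
#' computed with the symmetric product trick
#' \eqn{\mathrm{Tr}((\Sigma_a\Sigma_b)^{1/2}) =
#' \mathrm{Tr}((\Sigma_a^{1/2}\Sigma_b\Sigma_a^{1/2})^{1/2})}, which keeps
#' every eigendecomposition symmetric. Round-off eigenvalues below
#' `-tol * max(|lambda|)` raise an error; smaller ones are clamped to zero,
#' and a slightly negative total is clamped to zero.
#'
#' @param a,b `feature_stats` objects (or lists with `mu` and `cov`) of
#'   matching dimension.
#' @param tol Relative tolerance for the PSD check (default `1e-8`).
#' @return Non-negative scalar.
#' @export
frechet_distance <- function(a, b, tol = 1e-8) {
  if (length(a$mu) != length(b$mu)) stop("feature dimensions do not match")
  ca <- as.matrix(a$cov); cb <- as.matrix(b$cov)
  sa <- sym_sqrtm(ca, tol)
  cross <- sym_sqrtm(sa %*% cb %*% sa, tol)
  val <- sum((a$mu - b$mu)^2) + sum(diag(ca)) + sum(diag(cb)) - 2 * sum(diag(cross))
  max(val, 0)
}

#' Embed a patch collection and fit its feature Gaussian
#'
#' Applies a pluggable extractor (image -> fixed-length numeric vector) to
#' every patch image and returns the mean/covariance sufficient statistics.
#' The extractor contract mirrors deep-feature embeddings (pool3-style
#' activations) while remaining CPU-friendly; see [conv_feature_extractor()]
#' and [moment_feature_extractor()].
#'
#' @param images List of numeric matrices (patch images).
#' @param extractor Function mapping one image matrix to a numeric vector.
#' @return A `feature_stats` object.
#' @export
extract_features <- function(images, extractor = conv_feature_extractor()) {
  if (length(images) < 2L) stop("need at least 2 images")
  feats <- t(vapply(images, function(im) as.numeric(extractor(im)),
                    numeric(length(extractor(images[[1]])))))
  feature_stats(feats)
}

#' Fixed random convolutional feature extractor
#'
#' A small convolutional embedding with weights drawn deterministically from
#' `seed`: `n_filters` random 7x7 kernels are correlated with the image at
#' stride 4 (valid region), passed through ReLU, and average-pooled per
#' filter; filter-wise mean and standard deviation of the activations are
#' concatenated. Random convolutional features are a standard lightweight
#' stand-in for pretrained embeddings; the Frechet-distance arithmetic is
#' extractor-agnostic.
#'
#' @param n_filters Number of random kernels (default 16).
#' @param kernel Kernel side length (default 7).
#' @param stride Correlation stride (default 4).
#' @param seed Seed for the kernel draw (default 20240209).
#' @return A function: image matrix -> numeric vector of length
#'   `2 * n_filters`.
#' @export
conv_feature_extractor <- function(n_filters = 16L, kernel = 7L, stride = 4L,
                                   seed = 20240209L) {
  rng <- local_rng_state(seed)
  w <- matrix(stats::rnorm(kernel * kernel * n_filters), kernel * kernel, n_filters)
  w <- sweep(w, 2L, sqrt(colSums(w^2)), `/`)
  restore_rng_state(rng)
  function(im) {
    im <- as.matrix(im)
    if (nrow(im) < kernel || ncol(im) < kernel) {
      stop("image smaller than the extractor kernel")
    }
    rs <- seq(1L, nrow(im) - kernel + 1L, by = stride)
    cs <- seq(1L, ncol(im) - kernel + 1L, by = stride)
    # im2col: one column per window position
    off <- as.vector(outer(0:(kernel - 1L), (0:(kernel - 1L)) * nrow(im), `+`))
    base <- as.vector(outer(rs, (cs - 1L) * nrow(im), `+`))
    cols <- matrix(im[rep(base, each = length(off)) + off],
                   nrow = length(off))
    acts <- pmax(crossprod(cols, w), 0)
    sds <- if (nrow(acts) > 1L) apply(acts, 2L, stats::sd) else numeric(n_filters)
    c(colMeans(acts), sds)
  }
}

#' Hand-crafted 8-dimensional image statistic extractor
#'
#' Mean, SD, 10/50/90 percent quantiles, fraction of bright pixels
#' (> mean + SD), row-profile SD and column-profile SD. Useful when a
#' hand-checkable embedding is wanted.
#'
#' @return A function: image matrix -> numeric vector of length 8.
#' @export
moment_feature_extractor <- function() {
  function(im) {
    v <- as.numeric(im)
    q <- stats::quantile(v, c(0.1, 0.5, 0.9), names = FALSE)
    c(mean(v), stats::sd(v), q,
      mean(v > mean(v) + stats::sd(v)),
      stats::sd(rowMeans(as.matrix(im))), stats::sd(colMeans(as.matrix(im))))
  }
}

#' Structural similarity index between two images
#'
#' \deqn{SSIM(x, y) = \frac{(2\mu_x\mu_y + c_1)(2\sigma_{xy} + c_2)}
#'   {(\mu_x^2 + \mu_y^2 + c_1)(\sigma_x^2 + \sigma_y^2 + c_2)}}
#' with \eqn{c_1 = (k_1 L)^2}, \eqn{c_2 = (k_2 L)^2}. The default "global"
#' mode evaluates the formula once over the whole image; `window` > 0
#' averages it over sliding square windows (moving means/variances via
#' integral images). Variances use the population (1/n) convention.
#'
#' @param x,y Numeric matrices of identical shape.
#' @param k1,k2 Stabilization constants (defaults 0.01, 0.03).
#' @param L Dynamic range of the pixel values (default 1 for [0,1] images).
#' @param window `NULL` or 0 for global mode, otherwise the sliding-window
#'   side length.
#' @return Scalar in \eqn{(-1, 1]}.
#' @export
ssim <- function(x, y, k1 = 0.01, k2 = 0.03, L = 1, window = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!identical(dim(x), dim(y))) stop("x and y must have identical shape")
  if (L <= 0) stop("dynamic range L must be positive")
  c1 <- (k1 * L)^2
  c2 <- (k2 * L)^2
  ssim_from_moments <- function(mx, my, vx, vy, cxy) {
    ((2 * mx * my + c1) * (2 * cxy + c2)) /
      ((mx^2 + my^2 + c1) * (vx + vy + c2))
  }
  if (is.null(window) || window == 0) {
    n <- length(x)
    mx <- mean(x); my <- mean(y)
    vx <- sum((x - mx)^2) / n
    vy <- sum((y - my)^2) / n
    cxy <- sum((x - mx) * (y - my)) / n
    return(ssim_from_moments(mx, my, vx, vy, cxy))
  }
  w <- as.integer(window)
  if (w > min(dim(x))) stop("window larger than image")
  mx <- box_mean(x, w); my <- box_mean(y, w)
  vx <- box_mean(x^2, w) - mx^2
  vy <- box_mean(y^2, w) - my^2
  cxy <- box_mean(x * y, w) - mx * my
  mean(ssim_from_moments(mx, my, pmax(vx, 0), pmax(vy, 0), cxy))
}

# moving w x w window means via 2-D cumulative sums (valid positions only)
box_mean <- function(m, w) {
  cs <- apply(apply(m, 2L, cumsum), 1L, cumsum)  # transposed cumsum grid
  cs <- t(cs)
  pad <- matrix(0, nrow(cs) + 1L, ncol(cs) + 1L)
  pad[-1L, -1L] <- cs
  nr <- nrow(m) - w + 1L
  nc <- ncol(m) - w + 1L
  i <- seq_len(nr); j <- seq_len(nc)
  (pad[i + w, j + w, drop = FALSE] - pad[i, j + w, drop = FALSE] -
     pad[i + w, j, drop = FALSE] + pad[i, j, drop = FALSE]) / (w * w)
}

#' Mean pairwise SSIM of a patch collection (mode-collapse probe)
#'
#' Averages [ssim()] over all unordered pairs of the collection; a value
#' near 1 across many generated samples indicates mode collapse. For large
#' collections a seeded random subsample of pairs can be used.
#'
#' @param images List of numeric matrices.
#' @param max_pairs If the number of unordered pairs exceeds this, a random
#'   subsample of this size is scored (default 50000).
#' @param seed Seed for the pair subsample (default 1).
#' @param ... Passed to [ssim()].
#' @return List with `mean_ssim`, `n_images`, `n_pairs_scored`.
#' @export
mean_pairwise_ssim <- function(images, max_pairs = 50000L, seed = 1L, ...) {
  n <- length(images)
  if (n < 2L) stop("need at least 2 images")
  pairs <- utils::combn(n, 2L)
  if (ncol(pairs) > max_pairs) {
    rng <- local_rng_state(seed)
    pairs <- pairs[, sample.int(ncol(pairs), max_pairs), drop = FALSE]
    restore_rng_state(rng)
  }
  vals <- vapply(seq_len(ncol(pairs)), function(k) {
    ssim(images[[pairs[1L, k]]], images[[pairs[2L, k]]], ...)
  }, numeric(1))
  list(mean_ssim = mean(vals), n_images = n, n_pairs_scored = ncol(pairs))
}

# save the ambient RNG state, seed a scoped draw, and hand back a restorer;
# keeps helper randomness from perturbing user-visible streams
local_rng_state <- function(seed) {
  prev <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  prev
}

restore_rng_state <- function(prev) {
  if (is.null(prev)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", prev, envir = globalenv())
  }
  invisible(NULL)
}
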