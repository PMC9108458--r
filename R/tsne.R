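#' Calibrate pairwise similarities for t-SNE
#'
#' For every point i, the Gaussian bandwidth \eqn{\sigma_i} is found by
#' bisection on its precision so that the Shannon perplexity
#' \eqn{2^{H(p_{\cdot|i})}} of the conditional distribution
#' \deqn{p_{j|i} = \frac{\exp(-\|x_i-x_j\|^2/2\sigma_i^2)}
#'   {\sum_{k\ne i}\exp(-\|x_i-x_k\|^2/2\sigma_i^2)}}
#' matches the target. The joint similarity is the symmetrization
#' \eqn{p_{ij} = (p_{j|i} + p_{i|j}) / 2N} with \eqn{N} the number of
#' points, so that \eqn{\sum_{ij} p_{ij} = 1}.
#'
#' @param points Numeric matrix, rows = observations.
#' @param perplexity Target perplexity (default 30; must be < N).
#' @param tol Perplexity tolerance for the bisection (default 1e-5 on
#'   log-perplexity).
#' @param max_iter Bisection iterations cap (default 100).
#' @return An object of class `similarity_model`: `p_cond` (N x N, rows sum
#'   to 1, zero diagonal), `p_joint`, `bandwidths`, `perplexity`, `n`.
#' @export
calibrate_similarities <- function(points, perplexity = 30, tol = 1e-5,
                                   max_iter = 100L) {
  x <- as.matrix(points)
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 points")
  if (any(!is.finite(x))) stop("points must be finite")
  if (perplexity >= n) stop("perplexity must be smaller than the number of points")
  d2 <- as.matrix(stats::dist(x))^2
  target_h <- log2(perplexity)
  p_cond <- matrix(0, n, n)
  betas <- numeric(n)                      # precision 1/(2 sigma_i^2)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    beta <- 1
    lo <- 0; hi <- Inf
    for (it in seq_len(max_iter)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw <= 0) { hi <- beta; beta <- beta / 2; next }
      p <- w / sw
      h <- -sum(ifelse(p > 0, p * log2(p), 0))
      if (abs(h - target_h) < tol) break
      if (h > target_h) {                  # too flat -> increase precision
        lo <- beta
        beta <- if (is.finite(hi)) (lo + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- (lo + hi) / 2
      }
    }
    p_cond[i, -i] <- p
    betas[i] <- beta
  }
  p_joint <- (p_cond + t(p_cond)) / (2 * n)
  structure(
    list(p_cond = p_cond, p_joint = p_joint,
         bandwidths = sqrt(1 / (2 * betas)), perplexity = perplexity, n = n),
    class = "similarity_model"
  )
}

# low-dimensional Student-t similarities; returns q matrix, kernel w, sum
tsne_q <- function(y) {
  d2 <- unname(as.matrix(stats::dist(y)))^2
  w <- 1 / (1 + d2)
  diag(w) <- 0
  s <- sum(w)
  list(q = w / s, w = w, s = s)
}

tsne_kl_cost <- function(p, q) {
  m <- p > 0
  sum(p[m] * log(p[m] / pmax(q[m], 1e-12)))
}

# exact KL gradient: dC/dy_i = 4 sum_j (p_ij - q_ij) w_ij (y_i - y_j)
tsne_kl_grad <- function(p, y) {
  qq <- tsne_q(y)
  mult <- (p - qq$q) * qq$w
  n <- nrow(y)
  grad <- 4 * (diag(rowSums(mult)) - mult) %*% y
  list(grad = grad, cost = tsne_kl_cost(p, qq$q), q = qq$q)
}

# interpretation of a "Wasserstein" t-SNE cost: the 1-D Wasserstein distance
# between the sorted off-diagonal value distributions of P and Q, with a
# subgradient chained through q(y); labeled an interpretation in the docs
tsne_w_grad <- function(p, y) {
  qq <- tsne_q(y)
  n <- nrow(y)
  off <- upper.tri(p) | lower.tri(p)
  pv <- p[off]; qv <- qq$q[off]
  op <- order(pv); oq <- order(qv)
  cost <- sum(abs(pv[op] - qv[oq]))
  gq <- matrix(0, n, n)
  gvec <- numeric(length(qv))
  gvec[oq] <- sign(qv[oq] - pv[op])
  gq[off] <- gvec
  # chain rule: q = w / s  =>  dC/dw = (dC/dq - sum(dC/dq * q)) / s;
  # w_ij = (1 + d2)^{-1} => dw_ij/dy_i = -2 w_ij^2 (y_i - y_j); cells (i,j)
  # and (j,i) both move y_i, hence the symmetrization
  gw <- (gq - sum(gq * qq$q)) / qq$s
  S <- (gw + t(gw)) * qq$w^2
  grad <- -2 * (diag(rowSums(S)) - S) %*% y
  list(grad = grad, cost = cost, q = qq$q)
}

#' Run the t-SNE embedding
#'
#' Gradient descent with momentum from a seeded Gaussian initialization,
#' with early exaggeration (factor 4) for the first quarter of the
#' iterations and momentum switching from 0.5 to 0.8 at iteration 250 —
#' the classic schedule. `cost = "kl"` uses the exact Kullback-Leibler
#' gradient; `cost = "wasserstein"` is an interpretation that minimizes the
#' 1-D Wasserstein distance between the sorted similarity-value
#' distributions of P and Q (the replacement metric is not uniquely defined
#' on these objects; KL remains the reference mode).
#'
#' @param model A `similarity_model`.
#' @param iters Gradient iterations (default 500).
#' @param seed Seed for the initialization.
#' @param cost `"kl"` or `"wasserstein"`.
#' @param lr Learning rate (default 100).
#' @param groups Optional character vector of group labels, length N.
#' @return An object of class `embedding_result`: `coords` (N x 2), `q`,
#'   `cost_trace`, `groups`, `cost`.
#' @export
tsne_embed <- function(model, iters = 500L, seed = 1L,
                       cost = c("kl", "wasserstein"), lr = 100,
                       groups = NULL) {
  stopifnot(inherits(model, "similarity_model"))
  cost <- match.arg(cost)
  n <- model$n
  if (!is.null(groups) && length(groups) != n) {
    stop("groups must have one label per point")
  }
  prev <- local_rng_state(seed)
  on.exit(restore_rng_state(prev), add = TRUE)

  y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  inc <- matrix(0, n, 2)
  p <- model$p_joint
  exag_until <- max(1L, iters %/% 4L)
  grad_fn <- if (cost == "kl") tsne_kl_grad else tsne_w_grad
  trace <- numeric(iters)
  for (it in seq_len(iters)) {
    p_eff <- if (it <= exag_until) 4 * p else p
    gr <- grad_fn(p_eff, y)
    if (!all(is.finite(gr$grad))) {
      stop("t-SNE cost diverged at iteration ", it)
    }
    mom <- if (it < 250L) 0.5 else 0.8
    inc <- mom * inc - lr * gr$grad
    y <- y + inc
    y <- sweep(y, 2L, colMeans(y))
    trace[it] <- gr$cost        # cost under the (possibly exaggerated) p
  }
  qq <- tsne_q(y)
  structure(
    list(coords = y, q = qq$q, cost_trace = trace, groups = groups, cost = cost),
    class = "embedding_result"
  )
}

#' Tidy an embedding result
#'
#' @param x An `embedding_result`.
#' @param ... Unused.
#' @return Tibble with columns `group`, `x`, `y`.
#' @method tidy embedding_result
#' @export
tidy.embedding_result <- function(x, ...) {
  co <- x$coords
  tibble::tibble(group = x$groups %||% rep(NA_character_, nrow(co)),
                 x = co[, 1], y = co[, 2])
}

#' Scatter plot of a t-SNE embedding
#'
#' @param object An `embedding_result`.
#' @param ... Unused.
#' @return A ggplot object; points colored by group when groups are set.
#' @method autoplot embedding_result
#' @export
autoplot.embedding_result <- function(object, ...) {
  df <- tidy(object)
  gg <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y))
  if (!all(is.na(df$group))) {
    gg <- gg + ggplot2::geom_point(ggplot2::aes(color = .data$group), alpha = 0.8)
  } else {
    gg <- gg + ggplot2::geom_point(alpha = 0.8)
  }
  gg + ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2", color = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Embed real and generated patch images jointly
#'
#' Flattens the image channel of each patch to a feature vector, calibrates
#' similarities at the given perplexity, and embeds all groups together.
#'
#' @param patch_sets Named list of `patch_set`s, e.g.
#'   `list(real = ..., generated_nonprivate = ..., generated_private = ...)`.
#' @param perplexity Target perplexity (default 30).
#' @param iters,seed,cost Passed to [tsne_embed()].
#' @param max_per_group Cap on points per group (default 500), subsampled
#'   deterministically from `seed`.
#' @return An `embedding_result` with group labels.
#' @export
embed_patch_sets <- function(patch_sets, perplexity = 30, iters = 500L,
                             seed = 1L, cost = "kl", max_per_group = 500L) {
  stopifnot(is.list(patch_sets), !is.null(names(patch_sets)))
  prev <- local_rng_state(seed)
  feats <- list(); labels <- character(0)
  for (nm in names(patch_sets)) {
    ps <- patch_sets[[nm]]
    k <- min(length(ps$patches), max_per_group)
    pick <- sort(sample.int(length(ps$patches), k))
    feats[[nm]] <- t(vapply(ps$patches[pick],
                            function(p) as.numeric(p$image),
                            numeric(length(ps$patches[[1]]$image))))
    labels <- c(labels, rep(nm, k))
  }
  restore_rng_state(prev)
  x <- do.call(rbind, feats)
  model <- calibrate_similarities(x, perplexity = min(perplexity, nrow(x) - 1))
  tsne_embed(model, iters = iters, seed = seed, cost = cost, groups = labels)
}
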