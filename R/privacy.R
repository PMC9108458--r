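#' Privacy specification for DP-SGD critic training
#'
#' Bundles the four quantities that determine a differentially private
#' stochastic gradient descent run: the noise multiplier \eqn{\sigma} (ratio
#' of Gaussian noise scale to clipping norm), the per-sample gradient
#' clipping norm \eqn{C}, the Poisson sampling rate \eqn{q} (batch size over
#' dataset size), and the failure probability \eqn{\delta}.
#'
#' `noise_multiplier = 0` encodes the non-private arm: no noise is added and
#' the accountant reports \eqn{\epsilon = \infty}.
#'
#' @param noise_multiplier Noise multiplier \eqn{\sigma \ge 0} (dimensionless).
#' @param clip_norm Per-sample gradient L2 clipping norm \eqn{C > 0}.
#' @param sample_rate Poisson sampling rate \eqn{q \in (0, 1]}.
#' @param delta Failure probability \eqn{\delta \in (0, 1)}; conventionally
#'   the inverse of the training-set size.
#' @return An object of class `privacy_spec`.
#' @examples
#' privacy_spec(0.65, clip_norm = 1, sample_rate = 32 / 41000, delta = 1 / 41000)
#' @export
privacy_spec <- function(noise_multiplier, clip_norm = 1, sample_rate, delta) {
  stopifnot(
    is.numeric(noise_multiplier), length(noise_multiplier) == 1L, noise_multiplier >= 0,
    is.numeric(clip_norm), length(clip_norm) == 1L, clip_norm > 0,
    is.numeric(sample_rate), length(sample_rate) == 1L, sample_rate > 0, sample_rate <= 1,
    is.numeric(delta), length(delta) == 1L, delta > 0, delta < 1
  )
  structure(
    list(
      noise_multiplier = noise_multiplier,
      clip_norm = clip_norm,
      sample_rate = sample_rate,
      delta = delta
    ),
    class = "privacy_spec"
  )
}

#' @export
print.privacy_spec <- function(x, ...) {
  cat("<privacy_spec>\n")
  cat(sprintf("  noise multiplier sigma: %g%s\n", x$noise_multiplier,
              if (x$noise_multiplier == 0) "  (non-private, epsilon = Inf)" else ""))
  cat(sprintf("  clip norm C:            %g\n", x$clip_norm))
  cat(sprintf("  sample rate q:          %g\n", x$sample_rate))
  cat(sprintf("  delta:                  %g\n", x$delta))
  invisible(x)
}

#' Default Renyi-divergence order grid
#'
#' Integer orders 2..64 plus a fine grid just above 1. The integer orders
#' admit the exact binomial-expansion bound for the subsampled Gaussian
#' mechanism; the fine grid matters only for the unsubsampled mechanism at
#' very small privacy budgets.
#'
#' @param fine Include the fractional orders just above 1 (default `TRUE`).
#' @return Numeric vector of orders \eqn{\alpha > 1}.
#' @export
default_rdp_orders <- function(fine = TRUE) {
  orders <- as.numeric(2:64)
  if (fine) orders <- c(1.25, 1.5, 1.75, orders)
  orders
}

#' Renyi divergence of the Gaussian mechanism
#'
#' Closed-form order-\eqn{\alpha} Renyi divergence between two Gaussians of
#' common scale \eqn{\sigma} whose means differ by the mechanism sensitivity
#' (taken as 1): \eqn{\epsilon(\alpha) = \alpha / (2\sigma^2)}, in nats.
#'
#' @param order Renyi order(s) \eqn{\alpha > 1}; vectorized.
#' @param sigma Noise scale \eqn{\sigma > 0}.
#' @return \eqn{\epsilon(\alpha)} in nats, same length as `order`.
#' @export
rdp_gaussian <- function(order, sigma) {
  if (any(!is.finite(order)) || any(order <= 1)) {
    stop("Renyi order must be finite and > 1")
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("sigma must be a single positive number")
  }
  order / (2 * sigma^2)
}

# log(sum(exp(x))) without overflow; -Inf-safe
log_sum_exp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# exact integer-order bound: (1/(a-1)) * log E_{x~N(0,s^2)}[(mix/N(0,s^2))^a]
# expanded binomially; all terms kept in log space
rdp_subsampled_int <- function(alpha, sigma, q) {
  k <- 0:alpha
  log_terms <- lchoose(alpha, k) + k * log(q) +
    ifelse(alpha - k == 0, 0, (alpha - k) * log1p(-q)) +
    (k^2 - k) / (2 * sigma^2)
  log_sum_exp(log_terms) / (alpha - 1)
}

#' Renyi divergence of the Poisson-subsampled Gaussian mechanism
#'
#' Tight bound on the order-\eqn{\alpha} Renyi divergence between
#' \eqn{(1-q)\,N(0,\sigma^2) + q\,N(1,\sigma^2)} and \eqn{N(0,\sigma^2)},
#' the per-step privacy loss of DP-SGD with Poisson sampling at rate
#' \eqn{q}. Integer orders are evaluated exactly by the binomial expansion in
#' log space; a non-integer order \eqn{\alpha \ge 2} is bounded by linear
#' interpolation of \eqn{(\alpha-1)\epsilon(\alpha)} between the bracketing
#' integers (valid because that quantity is convex in \eqn{\alpha}).
#'
#' @param order Order(s) \eqn{\alpha \ge 2}; vectorized.
#' @param sigma Noise multiplier \eqn{\sigma > 0}.
#' @param q Sampling rate in \eqn{[0, 1]}.
#' @return \eqn{\epsilon(\alpha)} per step, in nats.
#' @export
rdp_subsampled_gaussian <- function(order, sigma, q) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("sigma must be a single positive number")
  }
  if (!is.numeric(q) || length(q) != 1L || q < 0 || q > 1) {
    stop("sample rate q must lie in [0, 1]")
  }
  if (any(order < 2)) stop("subsampled bound requires order >= 2")
  vapply(order, function(a) {
    if (q == 0) return(0)
    if (q == 1) return(rdp_gaussian(a, sigma))
    if (a == floor(a)) return(rdp_subsampled_int(as.integer(a), sigma, q))
    lo <- floor(a); hi <- ceiling(a)
    flo <- (lo - 1) * rdp_subsampled_int(as.integer(lo), sigma, q)
    fhi <- (hi - 1) * rdp_subsampled_int(as.integer(hi), sigma, q)
    w <- a - lo
    ((1 - w) * flo + w * fhi) / (a - 1)
  }, numeric(1))
}

#' Create an empty Renyi-DP ledger
#'
#' The ledger accumulates per-order Renyi privacy loss \eqn{\epsilon(\alpha)}
#' over composed mechanism invocations; composition is exactly additive per
#' order.
#'
#' @param orders Order grid \eqn{\alpha > 1} (default [default_rdp_orders()]).
#' @return An object of class `rdp_ledger` with fields `orders`, `eps_rdp`,
#'   `steps`.
#' @export
rdp_ledger <- function(orders = default_rdp_orders()) {
  if (any(orders <= 1)) stop("all orders must exceed 1")
  if (anyDuplicated(orders)) stop("orders must be distinct")
  structure(
    list(orders = as.numeric(orders),
         eps_rdp = numeric(length(orders)),
         steps = 0L),
    class = "rdp_ledger"
  )
}

#' Compose mechanism invocations onto a ledger
#'
#' Adds `n_steps` copies of a per-step Renyi loss curve to the ledger
#' (additive composition per order).
#'
#' @param ledger An [rdp_ledger()].
#' @param per_step_eps Per-step \eqn{\epsilon(\alpha)}, one value per ledger
#'   order (in ledger order).
#' @param n_steps Number of composed invocations (\eqn{\ge 0}).
#' @return The updated ledger.
#' @export
compose <- function(ledger, per_step_eps, n_steps = 1L) {
  stopifnot(inherits(ledger, "rdp_ledger"), n_steps >= 0)
  if (length(per_step_eps) != length(ledger$orders)) {
    stop("per_step_eps must match the ledger's order grid (",
         length(ledger$orders), " orders)")
  }
  if (any(per_step_eps < 0)) stop("per-step Renyi losses must be non-negative")
  ledger$eps_rdp <- ledger$eps_rdp + n_steps * per_step_eps
  ledger$steps <- ledger$steps + as.integer(n_steps)
  ledger
}

#' Convert an RDP ledger to an (epsilon, delta)-DP report
#'
#' Evaluates, at every ledger order, the conversion
#' \deqn{\epsilon' = \epsilon(\alpha) + \log\frac{\alpha-1}{\alpha} -
#'   \frac{\log\delta + \log\alpha}{\alpha - 1}}
#' and returns the minimum over the grid together with its arg-min order.
#' `conversion = "classic"` instead uses
#' \eqn{\epsilon' = \epsilon(\alpha) + \log(1/\delta)/(\alpha-1)}, the looser
#' form used by early DP-SGD accounting engines; it is provided so that
#' budgets published under that convention can be reproduced.
#'
#' @param ledger An [rdp_ledger()] with accumulated losses.
#' @param delta Target \eqn{\delta \in (0, 1)}.
#' @param conversion `"balle"` (default, the tight conversion above) or
#'   `"classic"`.
#' @return An object of class `dp_report`: list with `epsilon`, `delta`,
#'   `best_order`, `steps`.
#' @export
rdp_to_dp <- function(ledger, delta, conversion = c("balle", "classic")) {
  stopifnot(inherits(ledger, "rdp_ledger"))
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0 || delta >= 1) {
    stop("delta must lie in (0, 1)")
  }
  conversion <- match.arg(conversion)
  if (length(ledger$orders) == 0L) stop("ledger has an empty order grid")
  a <- ledger$orders
  e <- ledger$eps_rdp
  eps_dp <- switch(conversion,
    balle = e + log((a - 1) / a) - (log(delta) + log(a)) / (a - 1),
    classic = e - log(delta) / (a - 1)
  )
  if (all(!is.finite(eps_dp))) {
    return(structure(list(epsilon = Inf, delta = delta, best_order = NA_real_,
                          steps = ledger$steps, conversion = conversion),
                     class = "dp_report"))
  }
  i <- which.min(eps_dp)
  structure(
    list(epsilon = eps_dp[[i]], delta = delta, best_order = a[[i]],
         steps = ledger$steps, conversion = conversion),
    class = "dp_report"
  )
}

#' @export
print.dp_report <- function(x, ...) {
  cat("<dp_report>\n")
  cat(sprintf("  epsilon: %s  (delta = %g)\n",
              if (is.finite(x$epsilon)) sprintf("%.4f", x$epsilon) else "Inf", x$delta))
  cat(sprintf("  best order alpha: %s,  composed steps: %d,  conversion: %s\n",
              format(x$best_order), x$steps, x$conversion))
  invisible(x)
}

#' Run the full DP-SGD accountant in one call
#'
#' Composes the subsampled-Gaussian per-step loss over `steps` critic updates
#' and converts to \eqn{(\epsilon, \delta)}-DP. A zero noise multiplier
#' bypasses the ledger and reports \eqn{\epsilon = \infty} (the non-private
#' arm).
#'
#' @param noise_multiplier \eqn{\sigma \ge 0}.
#' @param sample_rate Poisson sampling rate \eqn{q}.
#' @param delta Target \eqn{\delta}.
#' @param steps Number of composed critic updates.
#' @param orders Order grid; integer orders only are used when subsampling
#'   (defaults to 2..64).
#' @param conversion Passed to [rdp_to_dp()].
#' @return A `dp_report`.
#' @examples
#' account_dp(0.65, sample_rate = 32 / 41000, delta = 1 / 41000, steps = 1000)
#' @export
account_dp <- function(noise_multiplier, sample_rate, delta, steps,
                       orders = default_rdp_orders(fine = FALSE),
                       conversion = c("balle", "classic")) {
  conversion <- match.arg(conversion)
  if (noise_multiplier == 0) {
    return(structure(list(epsilon = Inf, delta = delta, best_order = NA_real_,
                          steps = as.integer(steps), conversion = conversion),
                     class = "dp_report"))
  }
  led <- rdp_ledger(orders)
  per_step <- rdp_subsampled_gaussian(led$orders, noise_multiplier, sample_rate)
  led <- compose(led, per_step, steps)
  rdp_to_dp(led, delta, conversion)
}

#' Clip per-sample gradients and add Gaussian noise
#'
#' The DP-SGD aggregation step: every per-sample gradient is rescaled to L2
#' norm at most \eqn{C} (by \eqn{\min(1, C/\|g\|)}), the clipped gradients
#' are summed, isotropic Gaussian noise of per-coordinate scale
#' \eqn{\sigma C} is added, and the result is divided by the batch size.
#' With \eqn{\sigma = 0} this is the exact clipped mean. Noise is drawn from
#' the ambient RNG stream, so results are reproducible under `set.seed()`.
#'
#' @param per_sample_grads Numeric matrix (rows = samples) or list of equal
#'   length numeric vectors.
#' @param clip_norm Clipping norm \eqn{C > 0}.
#' @param sigma Noise multiplier \eqn{\sigma \ge 0}.
#' @return List with `grad` (the noised average gradient) and `clip_scale`
#'   (per-sample scale factors actually applied).
#' @export
clip_and_noise <- function(per_sample_grads, clip_norm, sigma) {
  if (is.list(per_sample_grads)) {
    per_sample_grads <- do.call(rbind, lapply(per_sample_grads, as.numeric))
  }
  if (!is.matrix(per_sample_grads) || nrow(per_sample_grads) == 0L) {
    stop("per_sample_grads must be a non-empty matrix or list of vectors")
  }
  stopifnot(clip_norm > 0, sigma >= 0)
  n <- nrow(per_sample_grads)
  norms <- sqrt(rowSums(per_sample_grads^2))
  scale <- pmin(1, clip_norm / pmax(norms, .Machine$double.eps))
  clipped <- per_sample_grads * scale
  agg <- colSums(clipped)
  if (sigma > 0) {
    agg <- agg + stats::rnorm(ncol(per_sample_grads), sd = sigma * clip_norm)
  }
  list(grad = agg / n, clip_scale = scale)
}

#' Serialize / restore an RDP ledger as JSON
#'
#' Full double precision is kept (17 significant digits) so that a
#' round-trip reproduces the ledger bit-exactly.
#'
#' @param ledger An `rdp_ledger`.
#' @param path File path.
#' @return `write_ledger` returns `path` invisibly; `read_ledger` the ledger.
#' @export
write_ledger <- function(ledger, path) {
  stopifnot(inherits(ledger, "rdp_ledger"))
  obj <- list(
    orders = sprintf("%.17g", ledger$orders),
    eps_rdp = sprintf("%.17g", ledger$eps_rdp),
    steps = ledger$steps
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ledger
#' @export
read_ledger <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(orders = as.numeric(obj$orders),
         eps_rdp = as.numeric(obj$eps_rdp),
         steps = as.integer(obj$steps)),
    class = "rdp_ledger"
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an RDP ledger into a tibble
#'
#' @param x An `rdp_ledger`.
#' @param ... Unused.
#' @return A tibble with one row per Renyi order: `order`, `eps_rdp`, `steps`.
#' @method tidy rdp_ledger
#' @export
tidy.rdp_ledger <- function(x, ...) {
  tibble::tibble(order = x$orders, eps_rdp = x$eps_rdp, steps = x$steps)
}

#' One-row summary of a DP report
#'
#' @param x A `dp_report`.
#' @param ... Unused.
#' @return A one-row tibble: `epsilon`, `delta`, `best_order`, `steps`,
#'   `conversion`.
#' @method glance dp_report
#' @export
glance.dp_report <- function(x, ...) {
  tibble::tibble(epsilon = x$epsilon, delta = x$delta,
                 best_order = x$best_order, steps = x$steps,
                 conversion = x$conversion)
}
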