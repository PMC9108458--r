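#' U-Net training configuration
#'
#' @param lr Learning rate (RMSprop).
#' @param dropout Dropout rate applied at the bottleneck during training.
#' @param augment Label-consistent flips / 90-degree rotations on each
#'   training batch.
#' @param epochs Training epochs (default 15).
#' @param batch_size Minibatch size (default 32).
#' @param base_channels Narrowest channel width (default 8).
#' @param seed Integer seed.
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(lr = 1e-3, dropout = 0, augment = FALSE, epochs = 15L,
                       batch_size = 32L, base_channels = 8L, seed = 1L) {
  stopifnot(lr > 0, dropout >= 0, dropout < 1, epochs > 0, batch_size > 0)
  structure(
    list(lr = lr, dropout = dropout, augment = isTRUE(augment),
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         base_channels = as.integer(base_channels), seed = as.integer(seed)),
    class = "seg_config"
  )
}

#' The 8-configuration U-Net hyperparameter grid
#'
#' Crosses learning rate {1e-3, 1e-4}, dropout {0, 0.1} and augmentation
#' {off, on} — the three factors varied in the published selection protocol.
#'
#' @param ... Overrides passed to every [seg_config()] (e.g. `epochs`).
#' @return A tibble with columns `config_id`, `lr`, `dropout`, `augment`,
#'   and a list-column `config`.
#' @export
seg_config_grid <- function(...) {
  grid <- tidyr::expand_grid(lr = c(1e-3, 1e-4), dropout = c(0, 0.1),
                             augment = c(FALSE, TRUE))
  grid$config_id <- seq_len(nrow(grid))
  grid$config <- purrr::pmap(grid[, c("lr", "dropout", "augment")],
                             function(lr, dropout, augment) {
                               seg_config(lr = lr, dropout = dropout,
                                          augment = augment, ...)
                             })
  grid[, c("config_id", "lr", "dropout", "augment", "config")]
}

# U-Net with two downsampling stages and skip connections:
#   e1 = relu(conv3 1->c)            (P, P, c)
#   e2 = relu(conv4s2 c->2c)         (P/2, P/2, 2c)
#   e3 = relu(conv4s2 2c->4c)        (P/4, P/4, 4c)   <- dropout here
#   d2 = relu(conv3 4c->2c after 2x upsample), concat e2 -> 4c
#   d1 = relu(conv3 4c->c after 2x upsample),  concat e1 -> 2c
#   out = sigmoid(conv3 2c->1)
build_unet <- function(patch_size, base_channels = 8L) {
  c1 <- base_channels
  list(
    conv_e1 = nn_conv(1L, c1, 3L, 1L, 1L),
    conv_e2 = nn_conv(c1, 2L * c1, 4L, 2L, 1L),
    conv_e3 = nn_conv(2L * c1, 4L * c1, 4L, 2L, 1L),
    conv_d2 = nn_conv(4L * c1, 2L * c1, 3L, 1L, 1L),
    conv_d1 = nn_conv(4L * c1, c1, 3L, 1L, 1L),
    conv_out = nn_conv(2L * c1, 1L, 3L, 1L, 1L),
    patch_size = as.integer(patch_size), base_channels = as.integer(c1)
  )
}

unet_param_names <- c("conv_e1", "conv_e2", "conv_e3", "conv_d2", "conv_d1",
                      "conv_out")

relu_fwd <- function(x) list(out = pmax(x, 0), mask = x > 0)

unet_forward <- function(u, x, dropout = 0, train = FALSE) {
  cache <- list()
  f1 <- conv_forward(u$conv_e1, x);  a1 <- relu_fwd(f1$out)
  f2 <- conv_forward(u$conv_e2, a1$out); a2 <- relu_fwd(f2$out)
  f3 <- conv_forward(u$conv_e3, a2$out); a3 <- relu_fwd(f3$out)
  e3 <- a3$out
  drop_mask <- NULL
  if (train && dropout > 0) {
    drop_mask <- array(stats::runif(length(e3)) >= dropout, dim = dim(e3))
    e3 <- e3 * drop_mask / (1 - dropout)
  }
  up2 <- upsample2_forward(NULL, e3)
  f4 <- conv_forward(u$conv_d2, up2$out); a4 <- relu_fwd(f4$out)
  cat2 <- abind4(a4$out, a2$out)
  up1 <- upsample2_forward(NULL, cat2)
  f5 <- conv_forward(u$conv_d1, up1$out); a5 <- relu_fwd(f5$out)
  cat1 <- abind4(a5$out, a1$out)
  f6 <- conv_forward(u$conv_out, cat1)
  prob <- 1 / (1 + exp(-f6$out))
  list(prob = prob,
       cache = list(f1 = f1, a1 = a1, f2 = f2, a2 = a2, f3 = f3, a3 = a3,
                    drop_mask = drop_mask, dropout = dropout, up2 = up2,
                    f4 = f4, a4 = a4, up1 = up1, f5 = f5, a5 = a5,
                    f6 = f6, prob = prob,
                    ch = c(d2 = dim(a4$out)[3], e2 = dim(a2$out)[3],
                           d1 = dim(a5$out)[3], e1 = dim(a1$out)[3])))
}

abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# gradient of the loss w.r.t. every conv's parameters, given dL/dprob
unet_backward <- function(u, cache, dprob) {
  g <- list()
  dlogit <- dprob * cache$prob * (1 - cache$prob)
  b6 <- conv_backward(u$conv_out, cache$f6$cache, dlogit)
  g$conv_out <- b6$grads
  ch <- cache$ch
  d_a5 <- b6$dx[, , seq_len(ch["d1"]), , drop = FALSE]
  d_a1_skip <- b6$dx[, , ch["d1"] + seq_len(ch["e1"]), , drop = FALSE]
  d_f5 <- d_a5 * cache$a5$mask
  b5 <- conv_backward(u$conv_d1, cache$f5$cache, d_f5)
  g$conv_d1 <- b5$grads
  d_cat2 <- upsample2_backward(NULL, cache$up1$cache, b5$dx)$dx
  d_a4 <- d_cat2[, , seq_len(ch["d2"]), , drop = FALSE]
  d_a2_skip <- d_cat2[, , ch["d2"] + seq_len(ch["e2"]), , drop = FALSE]
  d_f4 <- d_a4 * cache$a4$mask
  b4 <- conv_backward(u$conv_d2, cache$f4$cache, d_f4)
  g$conv_d2 <- b4$grads
  d_e3 <- upsample2_backward(NULL, cache$up2$cache, b4$dx)$dx
  if (!is.null(cache$drop_mask)) {
    d_e3 <- d_e3 * cache$drop_mask / (1 - cache$dropout)
  }
  d_f3 <- d_e3 * cache$a3$mask
  b3 <- conv_backward(u$conv_e3, cache$f3$cache, d_f3)
  g$conv_e3 <- b3$grads
  d_f2 <- (b3$dx + d_a2_skip) * cache$a2$mask
  b2 <- conv_backward(u$conv_e2, cache$f2$cache, d_f2)
  g$conv_e2 <- b2$grads
  d_f1 <- (b2$dx + d_a1_skip) * cache$a1$mask
  b1 <- conv_backward(u$conv_e1, cache$f1$cache, d_f1)
  g$conv_e1 <- b1$grads
  g
}

unet_flatten_params <- function(u) {
  unlist(lapply(unet_param_names, function(nm) c(as.numeric(u[[nm]]$W), u[[nm]]$b)))
}

unet_set_params <- function(u, theta) {
  pos <- 0L
  for (nm in unet_param_names) {
    nw <- length(u[[nm]]$W); nb <- length(u[[nm]]$b)
    u[[nm]]$W[] <- theta[(pos + 1L):(pos + nw)]
    u[[nm]]$b <- theta[(pos + nw + 1L):(pos + nw + nb)]
    pos <- pos + nw + nb
  }
  u
}

unet_flatten_grads <- function(g) {
  unlist(lapply(unet_param_names, function(nm) c(as.numeric(g[[nm]]$W), g[[nm]]$b)))
}

# soft Dice loss over the whole batch and its gradient w.r.t. probabilities
dice_loss_grad <- function(prob, target, smooth = 1) {
  A <- sum(prob * target)
  Bs <- sum(prob) + sum(target)
  loss <- 1 - (2 * A + smooth) / (Bs + smooth)
  dprob <- -(2 * target * (Bs + smooth) - (2 * A + smooth)) / (Bs + smooth)^2
  list(loss = loss, dprob = dprob)
}

# label-consistent augmentation: per-batch random flips / 90-degree rotation
augment_batch <- function(x, y) {
  if (stats::runif(1) < 0.5) { x <- x[rev(seq_len(dim(x)[1])), , , , drop = FALSE]
                               y <- y[rev(seq_len(dim(y)[1])), , , , drop = FALSE] }
  if (stats::runif(1) < 0.5) { x <- x[, rev(seq_len(dim(x)[2])), , , drop = FALSE]
                               y <- y[, rev(seq_len(dim(y)[2])), , , drop = FALSE] }
  if (stats::runif(1) < 0.5) { x <- aperm(x, c(2, 1, 3, 4)); y <- aperm(y, c(2, 1, 3, 4)) }
  list(x = x, y = y)
}

#' Train a U-Net on labeled image patches
#'
#' A slim two-stage encoder-decoder with skip connections, trained with the
#' soft Dice loss (1 - soft DSC) under RMSprop; Dice loss matches the
#' selection metric and tolerates the strong foreground/background
#' imbalance of vessel masks. Fully reproducible given `cfg$seed`.
#'
#' @param pairs A `patch_set` of training pairs (real or generated).
#' @param cfg A [seg_config()].
#' @param verbose Print per-epoch loss.
#' @return An object of class `unet_model`.
#' @export
train_unet <- function(pairs, cfg, verbose = FALSE) {
  stopifnot(inherits(pairs, "patch_set"), inherits(cfg, "seg_config"))
  if (length(pairs$patches) == 0L) stop("training set is empty")
  if (all(vapply(pairs$patches, function(p) sum(p$label) == 0, logical(1)))) {
    warning("every training label is empty; the model may be degenerate")
  }
  P <- nrow(pairs$patches[[1]]$image)
  if (P %% 4L != 0L) stop("patch size must be divisible by 4 for this U-Net")

  prev <- local_rng_state(cfg$seed)
  on.exit(restore_rng_state(prev), add = TRUE)

  xt <- patches_to_tensor(pairs$patches)
  x_all <- xt[, , 1L, , drop = FALSE]
  y_all <- xt[, , 2L, , drop = FALSE]
  n <- dim(x_all)[4]

  u <- build_unet(P, cfg$base_channels)
  theta <- unet_flatten_params(u)
  st <- rmsprop_state(length(theta))

  steps_per_epoch <- max(1L, ceiling(n / cfg$batch_size))
  trace <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    ep_loss <- 0
    for (t in seq_len(steps_per_epoch)) {
      idx <- perm[(((t - 1L) * cfg$batch_size) %% n + 1L):min(t * cfg$batch_size, n)]
      if (length(idx) == 0L) next
      xb <- x_all[, , , idx, drop = FALSE]
      yb <- y_all[, , , idx, drop = FALSE]
      if (cfg$augment) {
        ab <- augment_batch(xb, yb)
        xb <- ab$x; yb <- ab$y
      }
      fw <- unet_forward(u, xb, dropout = cfg$dropout, train = TRUE)
      lg <- dice_loss_grad(fw$prob, yb)
      g <- unet_backward(u, fw$cache, lg$dprob)
      upd <- rmsprop_step(theta, unet_flatten_grads(g), st, cfg$lr)
      theta <- upd$theta; st <- upd$state
      u <- unet_set_params(u, theta)
      ep_loss <- ep_loss + lg$loss
    }
    trace[epoch] <- ep_loss / steps_per_epoch
    if (verbose) message(sprintf("unet epoch %d/%d dice-loss %.4f",
                                 epoch, cfg$epochs, trace[epoch]))
  }

  structure(list(unet = u, config = cfg, loss_trace = trace, patch_size = P),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cat("<unet_model> P =", x$patch_size, "\n")
  cat(sprintf("  lr=%g dropout=%g augment=%s epochs=%d, final dice-loss %.4f\n",
              x$config$lr, x$config$dropout, x$config$augment, x$config$epochs,
              x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}

#' Predict patch probabilities
#'
#' @param object A `unet_model`.
#' @param images 4-D array (P, P, 1, N), 3-D (P, P, N), or a single matrix.
#' @param ... Unused.
#' @return Array of per-pixel vessel probabilities, shape (P, P, N).
#' @export
predict.unet_model <- function(object, images, ...) {
  if (is.matrix(images)) images <- array(images, c(dim(images), 1L, 1L))
  if (length(dim(images)) == 3L) {
    d <- dim(images)
    images <- array(images, c(d[1], d[2], 1L, d[3]))
  }
  pr <- unet_forward(object$unet, images, train = FALSE)$prob
  array(pr, dim(pr)[c(1, 2, 4)])
}

#' Segment a whole phantom volume slice by slice
#'
#' Each axial slice is tiled with P x P patches on a regular grid (tiles are
#' flush with the far edge, so border tiles may overlap), per-pixel
#' probabilities of overlapping tiles are averaged, and the stitched
#' probability map is thresholded at 0.5.
#'
#' @param model A `unet_model`.
#' @param vol A `phantom_volume`.
#' @param overlap Extra tile overlap in pixels (default 0; border tiles may
#'   still overlap to stay in bounds).
#' @param threshold Probability threshold (default 0.5).
#' @return Binary 3-D array congruent with `vol$intensity`.
#' @export
predict_volume <- function(model, vol, overlap = 0L, threshold = 0.5) {
  stopifnot(inherits(model, "unet_model"), inherits(vol, "phantom_volume"))
  P <- model$patch_size
  shp <- dim(vol$intensity)
  if (shp[1] < P || shp[2] < P) {
    stop("volume in-plane size ", shp[1], "x", shp[2], " is below patch size ", P)
  }
  starts <- function(n) {
    st <- seq(1L, max(n - P + 1L, 1L), by = max(P - overlap, 1L))
    unique(c(st, n - P + 1L))
  }
  rs <- starts(shp[1]); cs <- starts(shp[2])
  prob <- array(0, shp)
  cnt <- array(0, shp)
  tiles <- expand.grid(r = rs, c = cs)
  for (z in seq_len(shp[3])) {
    xb <- array(0, c(P, P, 1L, nrow(tiles)))
    for (k in seq_len(nrow(tiles))) {
      xb[, , 1L, k] <- vol$intensity[tiles$r[k]:(tiles$r[k] + P - 1L),
                                     tiles$c[k]:(tiles$c[k] + P - 1L), z]
    }
    pr <- unet_forward(model$unet, xb, train = FALSE)$prob
    for (k in seq_len(nrow(tiles))) {
      ri <- tiles$r[k]:(tiles$r[k] + P - 1L)
      ci <- tiles$c[k]:(tiles$c[k] + P - 1L)
      prob[ri, ci, z] <- prob[ri, ci, z] + pr[, , 1L, k]
      cnt[ri, ci, z] <- cnt[ri, ci, z] + 1
    }
  }
  (prob / cnt >= threshold) * 1L
}

#' Evaluate a segmentation model on phantom volumes
#'
#' @param model A `unet_model`.
#' @param volumes List of `phantom_volume`s.
#' @param dataset_tag Label for the report (e.g. "validation", "test_1").
#' @return An object of class `seg_report`: tibble of per-volume `dsc` and
#'   `bahd` plus attributes with mean/SD.
#' @export
evaluate_volumes <- function(model, volumes, dataset_tag = "test") {
  rows <- purrr::map_dfr(volumes, function(v) {
    pred <- predict_volume(model, v)
    b <- tryCatch(bahd(v$mask, pred), error = function(e) NA_real_)
    tibble::tibble(volume_id = v$subject_id, dsc = dsc(pred, v$mask),
                   bahd = b, dataset_tag = dataset_tag)
  })
  structure(rows, class = c("seg_report", class(rows)))
}

#' One-row summary of a segmentation report
#'
#' @param x A `seg_report`.
#' @param ... Unused.
#' @return One-row tibble: mean/SD of DSC and bAHD, n volumes, dataset tag.
#' @method glance seg_report
#' @export
glance.seg_report <- function(x, ...) {
  tibble::tibble(
    dataset_tag = x$dataset_tag[1], n_volumes = nrow(x),
    mean_dsc = mean(x$dsc), sd_dsc = stats::sd(x$dsc),
    mean_bahd = mean(x$bahd, na.rm = TRUE), sd_bahd = stats::sd(x$bahd, na.rm = TRUE))
}

#' Select the best U-Net from a candidate set by validation DSC
#'
#' Trains nothing itself: takes already-trained candidates, scores each on
#' the validation volumes, and returns the one with the highest mean DSC;
#' ties break by lower mean bAHD, then candidate order.
#'
#' @param candidates List of `unet_model`s.
#' @param validation_volumes List of `phantom_volume`s.
#' @return List with `model`, `index`, and `scores` (a tibble with one row
#'   per candidate).
#' @export
select_model <- function(candidates, validation_volumes) {
  stopifnot(length(candidates) >= 1L)
  scores <- purrr::map_dfr(seq_along(candidates), function(i) {
    rep <- evaluate_volumes(candidates[[i]], validation_volumes, "validation")
    g <- glance(rep)
    tibble::tibble(candidate = i, mean_dsc = g$mean_dsc, mean_bahd = g$mean_bahd)
  })
  ord <- order(-scores$mean_dsc, scores$mean_bahd, scores$candidate)
  best <- ord[1]
  list(model = candidates[[best]], index = best, scores = scores)
}
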