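#' Configuration for the differentially private Wasserstein GAN
#'
#' Default hyperparameters follow the published training recipe: latent
#' dimension 128, RMSprop learning rate 5e-5 for both networks, batch size
#' 32, five critic updates per generator update, critic weight clipping at
#' 0.01, 50 epochs at patch size 96. The WGAN weight clip (0.01, a Lipschitz
#' device) and the DP gradient clip (`privacy$clip_norm`, default 1) are
#' distinct parameters. The `"desk"` profile is a CPU-sized variant (patch
#' size 32, 20 epochs, slimmer channels) that keeps the same training
#' mechanics.
#'
#' @param profile `"paper"` or `"desk"`; sets size defaults which explicit
#'   arguments override.
#' @param patch_size Output side length P.
#' @param latent_dim Latent vector size (default 128).
#' @param lr RMSprop learning rate (default 5e-5).
#' @param batch_size Sampled batch size (default 32).
#' @param n_critic Critic updates per generator update (default 5).
#' @param wgan_clip Critic weight clipping bound (default 0.01).
#' @param epochs Training epochs.
#' @param base_channels Narrowest channel width of both networks.
#' @param n_stages Number of 2x upsampling / downsampling stages; `P /
#'   2^n_stages` must be a positive integer.
#' @param privacy A [privacy_spec()]; `noise_multiplier = 0` trains the
#'   non-private arm.
#' @param seed Integer seed controlling all training randomness.
#' @return An object of class `gan_config`.
#' @export
gan_config <- function(profile = c("paper", "desk"),
                       patch_size = NULL, latent_dim = 128L, lr = 5e-5,
                       batch_size = 32L, n_critic = 5L, wgan_clip = 0.01,
                       epochs = NULL, base_channels = NULL, n_stages = NULL,
                       privacy = NULL, seed = 1L) {
  profile <- match.arg(profile)
  defaults <- switch(profile,
    paper = list(patch_size = 96L, epochs = 50L, base_channels = 32L, n_stages = 5L),
    desk = list(patch_size = 32L, epochs = 20L, base_channels = 12L, n_stages = 4L))
  patch_size <- as.integer(patch_size %||% defaults$patch_size)
  epochs <- as.integer(epochs %||% defaults$epochs)
  base_channels <- as.integer(base_channels %||% defaults$base_channels)
  n_stages <- as.integer(n_stages %||% defaults$n_stages)
  if (patch_size %% (2^n_stages) != 0) {
    stop("patch size ", patch_size, " is not divisible by 2^", n_stages,
         "; choose n_stages so that P / 2^n_stages is a positive integer")
  }
  stopifnot(latent_dim > 0, lr > 0, batch_size > 0, n_critic > 0,
            wgan_clip > 0, epochs > 0, base_channels > 0, n_stages > 0)
  if (is.null(privacy)) {
    privacy <- privacy_spec(0, clip_norm = 1, sample_rate = 1e-3, delta = 1e-5)
  }
  structure(
    list(profile = profile, patch_size = patch_size, latent_dim = as.integer(latent_dim),
         lr = lr, batch_size = as.integer(batch_size), n_critic = as.integer(n_critic),
         wgan_clip = wgan_clip, epochs = epochs, base_channels = base_channels,
         n_stages = n_stages, privacy = privacy, seed = as.integer(seed)),
    class = "gan_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# channel schedule from the widest (coarsest) stage down to base_channels
gen_channel_schedule <- function(base_channels, n_stages) {
  rev(base_channels * 2^pmin(seq_len(n_stages) - 1L, 3L))
}

#' Build the generator network
#'
#' Maps a latent Gaussian vector (length `latent_dim`) through one linear
#' layer and `n_stages` nearest-neighbour-upsampling + 3x3 convolution
#' stages to a 2-channel P x P output (channel 1: image, channel 2: label
#' logits). The output head applies tanh rescaled to [0, 1] on the image
#' channel and a sigmoid on the label channel; binarization happens only at
#' synthesis time.
#'
#' @param cfg A [gan_config()].
#' @return An internal network object (list of layers) with attributes
#'   `base` (coarsest spatial size) and `n_params`.
#' @export
build_generator <- function(cfg) {
  stopifnot(inherits(cfg, "gan_config"))
  base <- cfg$patch_size %/% 2^cfg$n_stages
  ch <- gen_channel_schedule(cfg$base_channels, cfg$n_stages)
  layers <- list(
    nn_dense(cfg$latent_dim, base * base * ch[1]),
    nn_act("relu"),
    nn_reshape(c(base, base, ch[1]))
  )
  for (s in seq_len(cfg$n_stages)) {
    out_ch <- if (s < cfg$n_stages) ch[s + 1L] else cfg$base_channels
    layers <- c(layers, list(
      nn_upsample2(),
      nn_conv(ch_of(layers), out_ch, 3L, stride = 1L, pad = 1L),
      nn_act("relu")
    ))
  }
  layers <- c(layers, list(nn_conv(cfg$base_channels, 2L, 3L, stride = 1L, pad = 1L)))
  net <- list(layers = layers, role = "generator", patch_size = cfg$patch_size,
              latent_dim = cfg$latent_dim)
  attr(net, "base") <- base
  attr(net, "n_params") <- length(net_flatten_params(net))
  net
}

# channel count of the last conv/reshape layer added so far
ch_of <- function(layers) {
  for (l in rev(layers)) {
    if (l$type == "conv") return(l$out_ch)
    if (l$type == "reshape") return(l$shape[3])
  }
  stop("no channel-bearing layer yet")
}

#' Build the critic network
#'
#' Maps the 2-channel image-label pair through `n_stages` stride-2
#' convolutions (kernel 4, padding 1, LeakyReLU slope 0.2) and a final
#' linear layer to a single unbounded realness score. There are no
#' batch-coupling layers, so per-sample gradients are well defined.
#'
#' @param cfg A [gan_config()].
#' @return An internal network object.
#' @export
build_critic <- function(cfg) {
  stopifnot(inherits(cfg, "gan_config"))
  base <- cfg$patch_size %/% 2^cfg$n_stages
  ch <- rev(gen_channel_schedule(cfg$base_channels, cfg$n_stages))  # widen downward
  layers <- list()
  in_ch <- 2L
  for (s in seq_len(cfg$n_stages)) {
    layers <- c(layers, list(
      nn_conv(in_ch, ch[s], 4L, stride = 2L, pad = 1L),
      nn_act("leaky_relu", slope = 0.2)
    ))
    in_ch <- ch[s]
  }
  layers <- c(layers, list(nn_flatten(), nn_dense(base * base * in_ch, 1L)))
  net <- list(layers = layers, role = "critic", patch_size = cfg$patch_size)
  attr(net, "n_params") <- length(net_flatten_params(net))
  net
}

#' Wasserstein GAN losses
#'
#' `loss_G = -mean(D(x_gen))` (the generator maximizes the realness of its
#' samples) and `loss_D = mean(D(x_gen)) - mean(D(x_real))` (the critic
#' pushes generated scores down and real scores up).
#'
#' @param scores_real,scores_gen Numeric vectors of critic scores.
#' @return List with `loss_G` and `loss_D`.
#' @export
wgan_losses <- function(scores_real, scores_gen) {
  list(loss_G = -mean(scores_gen),
       loss_D = mean(scores_gen) - mean(scores_real))
}

# generator output head: channel 1 tanh -> [0,1], channel 2 sigmoid
gen_head_forward <- function(raw) {
  out <- raw
  out[, , 1L, , drop = FALSE] -> r1
  out[, , 2L, , drop = FALSE] -> r2
  out[, , 1L, ] <- (tanh(r1) + 1) / 2
  out[, , 2L, ] <- 1 / (1 + exp(-r2))
  out
}

gen_head_backward <- function(raw, head_out, dout) {
  draw <- dout
  t1 <- 2 * head_out[, , 1L, , drop = FALSE] - 1          # tanh value
  draw[, , 1L, ] <- dout[, , 1L, , drop = FALSE] * (1 - t1^2) / 2
  s <- head_out[, , 2L, , drop = FALSE]
  draw[, , 2L, ] <- dout[, , 2L, , drop = FALSE] * s * (1 - s)
  draw
}

# stack a list of labeled patches into an (P, P, 2, N) tensor
patches_to_tensor <- function(patches) {
  P <- nrow(patches[[1]]$image)
  x <- array(0, c(P, P, 2L, length(patches)))
  for (i in seq_along(patches)) {
    x[, , 1L, i] <- patches[[i]]$image
    x[, , 2L, i] <- patches[[i]]$label
  }
  x
}

# Per-sample critic parameter gradients of D(x_i), one row per sample.
# Samples never mix inside the network (no batch-coupling layers), so one
# batched forward + one batched backward suffice; per-sample parameter
# gradients fall out of the layer caches by slicing each sample's column
# block (conv) or column (dense). Row i equals the gradient a one-sample
# backward would produce; a loop-over-samples oracle locks this in tests.
critic_per_sample_grads <- function(critic, x) {
  N <- dim(x)[4]
  fw <- net_forward(critic, x)
  dout <- matrix(1, 1, N)                 # d(sum of scores)/d scores
  pieces <- vector("list", length(critic$layers))
  for (i in rev(seq_along(critic$layers))) {
    layer <- critic$layers[[i]]
    cache <- fw$caches[[i]]
    if (layer$type == "conv") {
      ii <- cache$ii
      dy <- matrix(aperm(dout, c(3, 1, 2, 4)), nrow = layer$out_ch)
      blk <- ii$oH * ii$oW
      g <- matrix(0, N, length(layer$W) + length(layer$b))
      for (s in seq_len(N)) {
        cols_s <- cache$cols[, ((s - 1L) * blk + 1L):(s * blk), drop = FALSE]
        dy_s <- dy[, ((s - 1L) * blk + 1L):(s * blk), drop = FALSE]
        g[s, ] <- c(as.numeric(cols_s %*% t(dy_s)), rowSums(dy_s))
      }
      pieces[[i]] <- g
      dout <- conv_backward(layer, cache, dout)$dx
    } else if (layer$type == "dense") {
      xc <- cache$x                        # in_dim x N
      dy <- dout                           # out_dim x N
      ind <- nrow(xc); outd <- nrow(dy)
      dW <- xc[rep(seq_len(ind), times = outd), , drop = FALSE] *
        dy[rep(seq_len(outd), each = ind), , drop = FALSE]
      pieces[[i]] <- cbind(t(dW), t(dy))
      dout <- dense_backward(layer, cache, dout)$dx
    } else {
      dout <- layer_backward(layer, cache, dout)$dx
    }
  }
  list(grads = do.call(cbind, pieces[net_param_layers(critic)]),
       scores = as.numeric(fw$out))
}

#' Train the differentially private Wasserstein GAN
#'
#' The loop: for every sampled critic batch (uniform with replacement, rate
#' `batch_size / |data|`), per-sample critic gradients of
#' `D(x_gen) - D(x_real)` are clipped to `privacy$clip_norm`, aggregated
#' with Gaussian noise of scale `sigma * C` ([clip_and_noise()]), and
#' applied with RMSprop; critic weights are then clipped to
#' `[-wgan_clip, wgan_clip]`; the Renyi ledger composes exactly one step.
#' Every `n_critic`-th critic batch the generator takes one (non-private)
#' RMSprop step on `-mean(D(G(z)))` — its update never touches real data
#' except through the critic, so it is post-processing and consumes no
#' budget. One epoch is `ceiling(|data| / batch_size)` critic batches.
#'
#' @param cfg A [gan_config()].
#' @param data A `patch_set` of real training patches.
#' @param verbose Print a line per epoch (default `FALSE`).
#' @return An object of class `gan_state`: generator/critic networks, the
#'   config, the `rdp_ledger`, a `dp_report`, and a per-step loss tibble.
#' @export
train_gan <- function(cfg, data, verbose = FALSE) {
  stopifnot(inherits(cfg, "gan_config"), inherits(data, "patch_set"))
  if (length(data$patches) == 0L) stop("training data is empty")
  P <- nrow(data$patches[[1]]$image)
  if (P != cfg$patch_size) {
    stop("data patch size ", P, " does not match config patch size ", cfg$patch_size)
  }

  prev <- local_rng_state(cfg$seed)
  on.exit(restore_rng_state(prev), add = TRUE)

  x_all <- patches_to_tensor(data$patches)
  n_data <- dim(x_all)[4]
  B <- min(cfg$batch_size, n_data)
  sample_rate <- B / n_data
  sigma <- cfg$privacy$noise_multiplier
  C <- cfg$privacy$clip_norm

  gen <- build_generator(cfg)
  cri <- build_critic(cfg)
  th_g <- net_flatten_params(gen)
  th_d <- net_flatten_params(cri)
  st_g <- rmsprop_state(length(th_g))
  st_d <- rmsprop_state(length(th_d))

  ledger <- rdp_ledger(default_rdp_orders(fine = FALSE))
  per_step_eps <- if (sigma > 0) {
    rdp_subsampled_gaussian(ledger$orders, sigma, sample_rate)
  } else NULL

  steps_per_epoch <- ceiling(n_data / B)
  loss_rows <- vector("list", cfg$epochs * steps_per_epoch)
  step <- 0L

  gen_batch <- function(nb, keep_cache = FALSE) {
    z <- matrix(stats::rnorm(cfg$latent_dim * nb), cfg$latent_dim, nb)
    fw <- net_forward(gen, z, keep_cache = keep_cache)
    list(z = z, raw = fw$out, caches = fw$caches, out = gen_head_forward(fw$out))
  }

  for (epoch in seq_len(cfg$epochs)) {
    for (t in seq_len(steps_per_epoch)) {
      step <- step + 1L
      idx <- sample.int(n_data, B, replace = TRUE)
      x_real <- x_all[, , , idx, drop = FALSE]
      gb <- gen_batch(B)

      g_gen <- critic_per_sample_grads(cri, gb$out)
      g_real <- critic_per_sample_grads(cri, x_real)
      # per-sample loss gradient: d(D(x_gen,i) - D(x_real,i))/d theta;
      # clip_and_noise divides the noised sum by B, matching d loss_D/d theta
      agg <- clip_and_noise(g_gen$grads - g_real$grads, C, sigma)
      upd <- rmsprop_step(th_d, agg$grad, st_d, cfg$lr)
      th_d <- upd$theta; st_d <- upd$state
      cri <- net_set_params(cri, th_d)
      cri <- net_clip_weights(cri, cfg$wgan_clip)
      th_d <- net_flatten_params(cri)
      if (sigma > 0) ledger <- compose(ledger, per_step_eps, 1L)

      losses <- wgan_losses(g_real$scores, g_gen$scores)  # pre-update scores
      if (!is.finite(losses$loss_D)) {
        stop("non-finite critic loss at step ", step,
             " (epoch ", epoch, "); sigma=", sigma)
      }

      loss_g_val <- NA_real_
      if (step %% cfg$n_critic == 0L) {
        gb2 <- gen_batch(B, keep_cache = TRUE)
        cfw <- net_forward(cri, gb2$out)
        dscore <- matrix(-1 / B, 1L, B)           # d(-mean D)/d scores
        cbw <- net_backward(cri, cfw$caches, dscore)
        draw <- gen_head_backward(gb2$raw, gb2$out, cbw$dx)
        gbw <- net_backward(gen, gb2$caches, draw)
        gg <- grads_flatten(gen, gbw$grads)
        updg <- rmsprop_step(th_g, gg, st_g, cfg$lr)
        th_g <- updg$theta; st_g <- updg$state
        gen <- net_set_params(gen, th_g)
        loss_g_val <- -mean(as.numeric(cfw$out))
      }
      loss_rows[[step]] <- tibble::tibble(
        epoch = epoch, step = step, loss_D = losses$loss_D, loss_G = loss_g_val)
    }
    if (verbose) {
      message(sprintf("epoch %d/%d  loss_D=%.4f", epoch, cfg$epochs,
                      loss_rows[[step]]$loss_D))
    }
  }

  report <- if (sigma > 0) {
    rdp_to_dp(ledger, cfg$privacy$delta)
  } else {
    structure(list(epsilon = Inf, delta = cfg$privacy$delta,
                   best_order = NA_real_, steps = ledger$steps,
                   conversion = "balle"), class = "dp_report")
  }

  structure(
    list(generator = gen, critic = cri, config = cfg, ledger = ledger,
         dp_report = report, losses = dplyr::bind_rows(loss_rows),
         epochs_run = cfg$epochs),
    class = "gan_state"
  )
}

#' @export
print.gan_state <- function(x, ...) {
  cat("<gan_state>\n")
  cat(sprintf("  P=%d, epochs=%d, sigma=%g, critic steps=%d\n",
              x$config$patch_size, x$epochs_run,
              x$config$privacy$noise_multiplier, x$ledger$steps))
  cat(sprintf("  epsilon=%s (delta=%g)\n",
              if (is.finite(x$dp_report$epsilon)) sprintf("%.3f", x$dp_report$epsilon)
              else "Inf", x$dp_report$delta))
  invisible(x)
}

#' Tidy the per-step loss trace of a trained GAN
#'
#' @param x A `gan_state`.
#' @param ... Unused.
#' @return Tibble with columns `epoch`, `step`, `loss_D`, `loss_G`.
#' @method tidy gan_state
#' @export
tidy.gan_state <- function(x, ...) x$losses

#' One-row summary of a trained GAN
#'
#' @param x A `gan_state`.
#' @param ... Unused.
#' @return One-row tibble: sigma, epsilon, delta, critic steps, final losses.
#' @method glance gan_state
#' @export
glance.gan_state <- function(x, ...) {
  last_d <- x$losses$loss_D[nrow(x$losses)]
  last_g <- rev(x$losses$loss_G[!is.na(x$losses$loss_G)])[1]
  tibble::tibble(
    noise_multiplier = x$config$privacy$noise_multiplier,
    epsilon = x$dp_report$epsilon, delta = x$dp_report$delta,
    critic_steps = x$ledger$steps, loss_D = last_d, loss_G = last_g %||% NA_real_)
}

#' Synthesize labeled patches from a trained generator
#'
#' Draws `n` latent vectors, runs the generator, keeps the image channel in
#' [0, 1], and binarizes the label channel at 0.5.
#'
#' @param state A `gan_state`.
#' @param n Number of patches (default 41000, the published protocol size).
#' @param seed Seed for the latent draws.
#' @param batch Forward batch size (default 256).
#' @return A `patch_set` with `mode = "generated"`.
#' @export
synthesize <- function(state, n = 41000L, seed = 1L, batch = 256L) {
  stopifnot(inherits(state, "gan_state"))
  if (n <= 0) stop("n must be positive")
  prev <- local_rng_state(seed)
  on.exit(restore_rng_state(prev), add = TRUE)
  gen <- state$generator
  patches <- vector("list", n)
  done <- 0L
  while (done < n) {
    nb <- min(batch, n - done)
    z <- matrix(stats::rnorm(gen$latent_dim * nb), gen$latent_dim, nb)
    out <- gen_head_forward(net_forward(gen, z, keep_cache = FALSE)$out)
    for (i in seq_len(nb)) {
      patches[[done + i]] <- structure(
        list(image = out[, , 1L, i], label = (out[, , 2L, i] >= 0.5) * 1L,
             origin = list(subject_id = "synthetic", z = NA_integer_,
                           row = NA_integer_, col = done + i),
             mode = "generated"),
        class = "labeled_patch")
    }
    done <- done + nb
  }
  manifest <- tibble::tibble(
    subject_id = "synthetic", z = NA_integer_, row = NA_integer_,
    col = seq_len(n), mode = "generated",
    label_fraction = vapply(patches, function(p) mean(p$label), numeric(1)))
  structure(list(patches = patches, manifest = manifest), class = "patch_set")
}
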