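# derive a 31-bit child seed from a master seed and a named stream; a small
# multiplicative hash keeps streams distinct and reproducible
derive_seed <- function(master, stream, index = 0L) {
  h <- as.double(master %% 2147483647L)
  for (ch in utf8ToInt(paste0(stream, ":", index))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

#' Plan the privacy-utility sweep experiment
#'
#' Builds a fully seeded experiment plan: a cohort split, the arm list of
#' noise multipliers (0 encodes the non-private arm; the published sweep is
#' {0, 2, 1.5, 1.2, 1, 0.8, 0.725, 0.65}), repeats per private arm
#' (published: 5; the non-private arm runs once), and a scale profile.
#' The `"paper"` profile uses the published cohort split (41 training, 11
#' validation, 14 test subjects); `"desk"` scales to 8/2/3 subjects with 200
#' patches each (100 vessel-centered + 100 random), patch size 32, 20 GAN
#' epochs, 2 repeats, and a 2-configuration U-Net grid. Every seed any stage
#' consumes is derived deterministically from `master_seed` through named
#' streams (cohort, gan, unet, synthesis, tsne).
#'
#' @param config Either a named list or a path to a YAML file with any of
#'   the fields below; missing fields take the profile defaults.
#' @param profile `"desk"` (default) or `"paper"`.
#' @param master_seed Master seed (default 1).
#' @return An object of class `experiment_plan`; its `arms` field is a
#'   tibble with one row per (noise multiplier, repeat).
#' @export
plan_experiment <- function(config = list(), profile = NULL, master_seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  profile <- profile %||% config$profile %||% "desk"
  master_seed <- as.integer(master_seed %||% config$master_seed %||% 1L)
  defaults <- switch(profile,
    paper = list(n_train = 41L, n_val = 11L, n_test = 14L,
                 n_vessel_centered = 500L, n_random = 500L, patch_size = 96L,
                 gan_epochs = 50L, repeats = 5L, n_synth = 41000L,
                 unet_grid_size = 8L, unet_epochs = 15L,
                 volume_shape = c(312L, 384L, 127L)),
    desk = list(n_train = 8L, n_val = 2L, n_test = 3L,
                n_vessel_centered = 100L, n_random = 100L, patch_size = 32L,
                gan_epochs = 20L, repeats = 2L, n_synth = 2000L,
                unet_grid_size = 2L, unet_epochs = 8L,
                volume_shape = c(64L, 64L, 48L)),
    stop("unknown profile ", profile))
  cfg <- utils::modifyList(defaults, config[setdiff(names(config),
                                                    c("profile", "master_seed"))])
  cfg$noise_multipliers <- cfg$noise_multipliers %||%
    c(0, 2, 1.5, 1.2, 1, 0.8, 0.725, 0.65)
  stopifnot(cfg$n_train > 0, cfg$n_val > 0, cfg$n_test > 0, cfg$repeats >= 1)

  total <- cfg$n_train + cfg$n_val + cfg$n_test
  subj <- tibble::tibble(
    subject_id = sprintf("subj-%03d", seq_len(total)),
    split = rep(c("train", "validation", "test"),
                times = c(cfg$n_train, cfg$n_val, cfg$n_test)),
    seed = vapply(seq_len(total), function(i) derive_seed(master_seed, "cohort", i),
                  integer(1)))
  if (anyDuplicated(subj$subject_id)) stop("overlapping cohort splits")

  arms <- purrr::map_dfr(cfg$noise_multipliers, function(sig) {
    reps <- if (sig == 0) 1L else as.integer(cfg$repeats)
    tibble::tibble(
      noise_multiplier = sig, rep = seq_len(reps),
      gan_seed = vapply(seq_len(reps), function(r)
        derive_seed(master_seed, paste0("gan:", sig), r), integer(1)),
      unet_seed = vapply(seq_len(reps), function(r)
        derive_seed(master_seed, paste0("unet:", sig), r), integer(1)),
      synth_seed = vapply(seq_len(reps), function(r)
        derive_seed(master_seed, paste0("synthesis:", sig), r), integer(1)))
  })

  structure(
    list(profile = profile, master_seed = master_seed, settings = cfg,
         subjects = subj, arms = arms),
    class = "experiment_plan"
  )
}

#' @export
print.experiment_plan <- function(x, ...) {
  s <- x$settings
  cat("<experiment_plan>", x$profile, "profile, master seed", x$master_seed, "\n")
  cat(sprintf("  cohort: %d train / %d validation / %d test subjects\n",
              s$n_train, s$n_val, s$n_test))
  cat(sprintf("  patches per subject: %d vessel-centered + %d random, P=%d\n",
              s$n_vessel_centered, s$n_random, s$patch_size))
  cat(sprintf("  arms: sigma in {%s}, repeats (private arms): %d\n",
              paste(s$noise_multipliers, collapse = ", "), s$repeats))
  invisible(x)
}

#' Tidy an experiment plan's arm table
#'
#' @param x An `experiment_plan`.
#' @param ... Unused.
#' @return The arm tibble (noise multiplier, repeat, derived seeds).
#' @method tidy experiment_plan
#' @export
tidy.experiment_plan <- function(x, ...) x$arms

# build the cohort of phantom volumes and the pooled training patches
build_cohort <- function(plan) {
  s <- plan$settings
  vols <- purrr::map(seq_len(nrow(plan$subjects)), function(i) {
    row <- plan$subjects[i, ]
    generate_volume(seed = row$seed, shape = s$volume_shape,
                    n_vessels = s$n_vessels %||% 6L,
                    subject_id = row$subject_id)
  })
  names(vols) <- plan$subjects$subject_id
  split_of <- function(tag) vols[plan$subjects$split == tag]
  train_sets <- purrr::imap(split_of("train"), function(v, nm) {
    extract_patches(v, s$n_vessel_centered, s$n_random,
                    patch_size = s$patch_size,
                    seed = derive_seed(plan$master_seed, "patches", v$seed))
  })
  list(train_patches = bind_patch_sets(unname(train_sets)),
       train_volumes = split_of("train"),
       validation_volumes = split_of("validation"),
       test_volumes = split_of("test"))
}

# run one (sigma, repeat) arm against a prepared cohort
run_arm <- function(plan, cohort, sigma, gan_seed, unet_seed, synth_seed,
                    verbose = FALSE) {
  s <- plan$settings
  n_train_patches <- length(cohort$train_patches$patches)
  priv <- privacy_spec(sigma, clip_norm = 1,
                       sample_rate = min(1, 32 / n_train_patches),
                       delta = 1 / n_train_patches)
  cfg <- gan_config(profile = if (plan$profile == "paper") "paper" else "desk",
                    patch_size = s$patch_size, epochs = s$gan_epochs,
                    base_channels = s$gan_base_channels %||% NULL,
                    n_stages = s$gan_n_stages %||% NULL,
                    privacy = priv, seed = gan_seed)
  state <- train_gan(cfg, cohort$train_patches, verbose = verbose)
  synth <- synthesize(state, n = s$n_synth, seed = synth_seed)

  grid <- seg_config_grid(epochs = s$unet_epochs)[seq_len(s$unet_grid_size), ]
  models <- purrr::map(seq_len(nrow(grid)), function(i) {
    cfgu <- grid$config[[i]]
    cfgu$seed <- derive_seed(unet_seed, "grid", i)
    train_unet(synth, cfgu)
  })
  sel <- select_model(models, cohort$validation_volumes)
  test_report <- evaluate_volumes(sel$model, cohort$test_volumes, "test_1")

  extractor <- conv_feature_extractor()
  imgs_of <- function(ps, k) {
    pick <- seq_len(min(k, length(ps$patches)))
    lapply(ps$patches[pick], `[[`, "image")
  }
  n_fid <- s$n_fid %||% 200L
  fs_synth <- extract_features(imgs_of(synth, n_fid), extractor)
  fs_train <- extract_features(imgs_of(cohort$train_patches, n_fid), extractor)
  test_patches <- extract_patches(cohort$test_volumes[[1]],
                                  min(s$n_vessel_centered, 50L),
                                  min(s$n_random, 50L),
                                  patch_size = s$patch_size,
                                  seed = derive_seed(plan$master_seed, "fid-test", 1L))
  fs_test <- extract_features(imgs_of(test_patches, n_fid), extractor)
  fid_train <- frechet_distance(fs_train, fs_synth)
  fid_test <- frechet_distance(fs_test, fs_synth)
  ssim_probe <- mean_pairwise_ssim(imgs_of(synth, s$n_ssim %||% 100L))

  gl <- glance(test_report)
  tibble::tibble(
    noise_multiplier = sigma,
    epsilon = state$dp_report$epsilon,
    critic_steps = state$ledger$steps,
    mean_dsc = gl$mean_dsc, sd_dsc = gl$sd_dsc,
    mean_bahd = gl$mean_bahd, sd_bahd = gl$sd_bahd,
    fid_train = fid_train, fid_test = fid_test,
    fid_gap = fid_train - fid_test,
    mean_pairwise_ssim = ssim_probe$mean_ssim,
    selected_config = sel$index,
    gan_seed = gan_seed, unet_seed = unet_seed, synth_seed = synth_seed)
}

#' Run the full privacy-utility sweep
#'
#' For every arm (noise multiplier) and repeat: train the DP-WGAN, account
#' the privacy budget, synthesize labeled pairs, train the U-Net grid,
#' select by validation DSC, evaluate DSC/bAHD on the test volumes, and
#' compute FID against training and test patch pools plus the mean pairwise
#' SSIM mode-collapse probe. Arm failures are caught and recorded; the sweep
#' continues.
#'
#' @param plan An [plan_experiment()] result.
#' @param verbose Progress messages.
#' @return List with `arms` (tibble, one row per run; failed runs carry an
#'   `error` message), `summary` (mean (SD) per metric per arm), and
#'   `cohort_info`.
#' @export
run_sweep <- function(plan, verbose = FALSE) {
  stopifnot(inherits(plan, "experiment_plan"))
  cohort <- build_cohort(plan)
  rows <- purrr::map(seq_len(nrow(plan$arms)), function(i) {
    a <- plan$arms[i, ]
    if (verbose) message(sprintf("arm sigma=%g rep %d", a$noise_multiplier, a$rep))
    tryCatch(
      dplyr::mutate(run_arm(plan, cohort, a$noise_multiplier, a$gan_seed,
                            a$unet_seed, a$synth_seed, verbose = FALSE),
                    rep = a$rep, error = NA_character_),
      error = function(e) tibble::tibble(
        noise_multiplier = a$noise_multiplier, rep = a$rep,
        error = conditionMessage(e)))
  })
  arms <- dplyr::bind_rows(rows)
  ok <- arms[is.na(arms$error), ]
  summary <- if (nrow(ok) > 0) {
    dplyr::summarise(
      dplyr::group_by(ok, .data$noise_multiplier),
      epsilon = dplyr::first(.data$epsilon),
      mean_dsc = mean(.data$mean_dsc), sd_dsc = stats::sd(.data$mean_dsc),
      mean_bahd = mean(.data$mean_bahd), sd_bahd = stats::sd(.data$mean_bahd),
      mean_fid_train = mean(.data$fid_train), mean_fid_test = mean(.data$fid_test),
      mean_ssim = mean(.data$mean_pairwise_ssim), n_runs = dplyr::n(),
      .groups = "drop")
  } else tibble::tibble()
  list(arms = arms, summary = summary,
       cohort_info = list(n_train_patches = length(cohort$train_patches$patches),
                          subjects = plan$subjects))
}

#' Privacy accounting for the published GAN training recipe
#'
#' Convenience wrapper reproducing the accounting of the published
#' experiment: batch size 32 over 41,000 image-label pairs
#' (q = 32/41000), delta = 1/41000, and a critic-step count determined by
#' the epoch convention. `"per_generator_update"` (default) counts 5 critic
#' updates per generator iteration with ceiling(41000/32) generator
#' iterations per epoch; `"per_batch"` counts one critic update per sampled
#' batch (ceiling(41000/32) critic steps per epoch).
#'
#' @param noise_multiplier Noise multiplier sigma.
#' @param epochs Number of training epochs.
#' @param n_samples Training-set size (default 41000).
#' @param batch_size Batch size (default 32).
#' @param n_critic Critic updates per generator update (default 5).
#' @param convention `"per_generator_update"` or `"per_batch"`.
#' @param conversion Passed to [rdp_to_dp()]; `"classic"` reproduces the
#'   conversion used by the accounting engines of the publication era.
#' @return A `dp_report`.
#' @export
account_training_run <- function(noise_multiplier, epochs,
                                 n_samples = 41000L, batch_size = 32L,
                                 n_critic = 5L,
                                 convention = c("per_generator_update", "per_batch"),
                                 conversion = c("balle", "classic")) {
  convention <- match.arg(convention)
  conversion <- match.arg(conversion)
  batches <- ceiling(n_samples / batch_size)
  steps <- switch(convention,
    per_generator_update = n_critic * batches * epochs,
    per_batch = batches * epochs)
  account_dp(noise_multiplier, sample_rate = batch_size / n_samples,
             delta = 1 / n_samples, steps = steps, conversion = conversion)
}

#' Write sweep outputs to a results directory
#'
#' Emits `arms.csv`, `summary_table.csv` and `accounting.json`.
#'
#' @param sweep A [run_sweep()] result.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_sweep_results <- function(sweep, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(sweep$arms, file.path(dir, "arms.csv"), row.names = FALSE)
  utils::write.csv(sweep$summary, file.path(dir, "summary_table.csv"),
                   row.names = FALSE)
  acc <- sweep$arms[is.na(sweep$arms$error),
                    c("noise_multiplier", "rep", "epsilon", "critic_steps")]
  jsonlite::write_json(acc, file.path(dir, "accounting.json"), digits = NA,
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(dir)
}

#' Boxplot of DSC across sweep arms
#'
#' @param sweep A [run_sweep()] result.
#' @return A ggplot object: per-arm DSC distribution over repeats.
#' @export
plot_sweep_dsc <- function(sweep) {
  ok <- sweep$arms[is.na(sweep$arms$error), ]
  ggplot2::ggplot(ok, ggplot2::aes(factor(.data$noise_multiplier), .data$mean_dsc)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "noise multiplier", y = "mean test DSC") +
    ggplot2::theme_minimal()
}
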