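#' Generate a synthetic vascular phantom volume
#'
#' Builds a 3-D grayscale volume that emulates the patch statistics of
#' time-of-flight angiography: bright curvilinear tubular structures on a
#' darker noisy background. Each vessel is a random-walk centerline with a
#' smoothly varying radius in [1, 4] voxels, rendered with a Gaussian
#' brightness profile; the binary mask is the exact rasterized tube support
#' (voxel centers within the local radius of the centerline). The background
#' has mean `bg_mean` with additive Gaussian noise of SD `noise_level`; the
#' vessel core intensity exceeds the background mean by at least three
#' background SDs before noise. Intensities are min-max normalized to [0, 1]
#' per volume.
#'
#' @param seed Integer seed; identical seeds give bit-identical volumes.
#' @param shape Integer 3-vector (nx, ny, nz), each axis >= 32.
#' @param n_vessels Number of tubes (>= 0; 0 gives an empty mask).
#' @param noise_level Background noise SD as a fraction of the dynamic
#'   range, in [0, 0.5].
#' @param spacing Voxel size per axis in mm (default c(0.5, 0.5, 0.5)).
#' @param subject_id Opaque identifier (default derived from the seed).
#' @return An object of class `phantom_volume`: list with `intensity`
#'   (3-D array in [0,1]), `mask` (3-D 0/1 array), `spacing`, `subject_id`,
#'   `seed`.
#' @examples
#' vol <- generate_volume(seed = 1, shape = c(48, 48, 32), n_vessels = 3)
#' mean(vol$mask)
#' @export
generate_volume <- function(seed, shape = c(64, 64, 48), n_vessels = 6,
                            noise_level = 0.08, spacing = c(0.5, 0.5, 0.5),
                            subject_id = sprintf("phantom-%06d", seed)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 32L)) {
    stop("shape must be a 3-vector with every axis >= 32 ",
         "(smaller axes cannot hold a patch)")
  }
  if (n_vessels < 0) stop("n_vessels must be >= 0")
  if (noise_level < 0 || noise_level > 0.5) stop("noise_level must lie in [0, 0.5]")

  prev <- local_rng_state(seed)
  on.exit(restore_rng_state(prev), add = TRUE)

  bg_mean <- 0.25
  bg_sd <- max(noise_level, 0.02)
  vessel_core <- bg_mean + max(3 * bg_sd, 0.35)   # >= bg mean + 3 SD pre-noise

  intens <- array(0, dim = shape)
  mask <- array(0L, dim = shape)

  if (n_vessels >= 1) {
    for (v in seq_len(n_vessels)) {
      cl <- random_walk_centerline(shape)
      rad <- smooth_radius(nrow(cl))
      tube <- rasterize_tube(shape, cl, rad)
      mask[tube$idx] <- 1L
      intens[tube$idx] <- pmax(intens[tube$idx], vessel_core * tube$profile)
    }
  }

  noise <- array(stats::rnorm(prod(shape), mean = bg_mean, sd = bg_sd), dim = shape)
  out <- ifelse(mask == 1L, intens, 0) + noise
  rng <- range(out)
  out <- (out - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)

  structure(
    list(intensity = out, mask = mask, spacing = as.numeric(spacing),
         subject_id = subject_id, seed = as.integer(seed)),
    class = "phantom_volume"
  )
}

# a smooth 3-D random walk across the volume, returned as an n x 3 matrix of
# (possibly fractional) voxel coordinates sampled densely along the path
random_walk_centerline <- function(shape, step = 0.5, momentum = 0.92) {
  span <- min(shape)
  n_steps <- as.integer(4 * span)
  start <- stats::runif(3, min = shape * 0.15, max = shape * 0.85)
  dir <- stats::rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  pts <- matrix(0, n_steps, 3)
  p <- start
  for (i in seq_len(n_steps)) {
    turn <- stats::rnorm(3, sd = 0.35)
    dir <- momentum * dir + (1 - momentum) * turn
    dir <- dir / sqrt(sum(dir^2))
    p <- p + step * dir
    # reflect off the volume bounds with a small margin
    for (ax in 1:3) {
      if (p[ax] < 2) { p[ax] <- 2 + (2 - p[ax]); dir[ax] <- abs(dir[ax]) }
      if (p[ax] > shape[ax] - 1) {
        p[ax] <- (shape[ax] - 1) - (p[ax] - (shape[ax] - 1))
        dir[ax] <- -abs(dir[ax])
      }
    }
    pts[i, ] <- p
  }
  pts
}

# smoothly varying per-point radius in [1, 4] voxels
smooth_radius <- function(n, lo = 1, hi = 4) {
  base <- stats::runif(1, lo, hi)
  wob <- stats::filter(stats::rnorm(n, sd = 0.6), rep(1 / 25, 25), sides = 2)
  wob[is.na(wob)] <- 0
  pmin(pmax(base + as.numeric(wob), lo), hi)
}

# rasterize a tube: voxels whose center lies within the local radius of the
# centerline; returns linear indices and a Gaussian cross-sectional profile
rasterize_tube <- function(shape, centerline, radius) {
  idx_parts <- vector("list", nrow(centerline))
  prof_parts <- vector("list", nrow(centerline))
  for (i in seq_len(nrow(centerline))) {
    c0 <- centerline[i, ]
    r <- radius[i]
    lo <- pmax(floor(c0 - r), 1)
    hi <- pmin(ceiling(c0 + r), shape)
    xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
    dx2 <- (xs - c0[1])^2
    dy2 <- (ys - c0[2])^2
    dz2 <- (zs - c0[3])^2
    d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    inside <- which(d2 <= r^2)
    if (length(inside) == 0L) next
    # linear index into the full volume for each in-window voxel
    full <- outer(outer(xs, (ys - 1L) * shape[1], `+`),
                  (zs - 1L) * shape[1] * shape[2], `+`)
    idx_parts[[i]] <- as.integer(full[inside])
    prof_parts[[i]] <- exp(-d2[inside] / (2 * (r / 1.5)^2))
  }
  idx <- unlist(idx_parts, use.names = FALSE)
  prof <- unlist(prof_parts, use.names = FALSE)
  if (is.null(idx) || length(idx) == 0L) {
    return(list(idx = integer(0), profile = numeric(0)))
  }
  # keep the maximum profile value where disks along the centerline overlap
  o <- order(idx, -prof)
  keep <- !duplicated(idx[o])
  list(idx = idx[o][keep], profile = prof[o][keep])
}

#' @export
print.phantom_volume <- function(x, ...) {
  cat("<phantom_volume>", x$subject_id, "\n")
  cat(sprintf("  shape: %s, spacing: %s mm\n",
              paste(dim(x$intensity), collapse = "x"),
              paste(x$spacing, collapse = "x")))
  cat(sprintf("  vessel voxel fraction: %.4f, seed: %d\n", mean(x$mask), x$seed))
  invisible(x)
}

#' Extract labeled 2-D patches from a phantom volume
#'
#' Cuts axial (z-slice) patches of size P x P together with their mask
#' crops. `n_vessel_centered` patches are sampled uniformly from positions
#' whose central mask voxel is 1; `n_random` patches uniformly from all
#' in-bounds positions. A patch at top-left (r, c) covers the half-open
#' window `[r, r+P) x [c, c+P)` in 0-based coordinates, with center at
#' `(r + P %/% 2, c + P %/% 2)`. Every (subject, z, row, col) origin is used
#' at most once across the whole set; collisions are resampled up to a retry
#' cap.
#'
#' @param vol A `phantom_volume`.
#' @param n_vessel_centered,n_random Quotas per sampling mode.
#' @param patch_size Side length P (default 96).
#' @param seed Integer seed for the position draws.
#' @return An object of class `patch_set`: list with `patches` (list of
#'   `labeled_patch`: `image`, `label`, `origin`, `mode`) and `manifest`
#'   (a tibble with one provenance row per patch).
#' @export
extract_patches <- function(vol, n_vessel_centered, n_random,
                            patch_size = 96L, seed = 1L) {
  stopifnot(inherits(vol, "phantom_volume"))
  P <- as.integer(patch_size)
  shp <- dim(vol$intensity)
  if (shp[1] < P || shp[2] < P) {
    stop("volume in-plane size ", shp[1], "x", shp[2],
         " cannot hold a ", P, "x", P, " patch")
  }
  half <- P %/% 2L
  # valid 0-based top-left rows/cols; centers are offsets + half
  max_r <- shp[1] - P      # top-left r in 0..max_r
  max_c <- shp[2] - P
  n_pos <- (max_r + 1L) * (max_c + 1L) * shp[3]

  prev <- local_rng_state(seed)
  on.exit(restore_rng_state(prev), add = TRUE)

  # candidate centers for vessel-centered mode: central mask voxel == 1 and
  # the full window in bounds
  if (n_vessel_centered > 0) {
    ctr <- which(vol$mask == 1L, arr.ind = TRUE)
    ok <- ctr[, 1] >= half + 1L & ctr[, 1] <= max_r + half + 1L &
      ctr[, 2] >= half + 1L & ctr[, 2] <= max_c + half + 1L
    cand <- ctr[ok, , drop = FALSE]
    if (nrow(cand) < n_vessel_centered) {
      stop("only ", nrow(cand), " vessel-centered candidate positions exist; ",
           n_vessel_centered, " requested (shortfall ",
           n_vessel_centered - nrow(cand), ")")
    }
  }

  seen <- new.env(hash = TRUE, parent = emptyenv())
  origin_key <- function(z, r, c) paste(z, r, c, sep = ":")
  take <- function(z, r, c) {        # 0-based r, c top-left; 1-based z
    key <- origin_key(z, r, c)
    if (!is.null(seen[[key]])) return(NULL)
    seen[[key]] <- TRUE
    img <- vol$intensity[(r + 1L):(r + P), (c + 1L):(c + P), z]
    lab <- vol$mask[(r + 1L):(r + P), (c + 1L):(c + P), z]
    list(image = img, label = lab, z = z, r = r, c = c)
  }

  patches <- vector("list", n_vessel_centered + n_random)
  rows <- vector("list", n_vessel_centered + n_random)
  n_got <- 0L
  retry_cap <- 100L * (n_vessel_centered + n_random) + 1000L
  tries <- 0L

  draw_mode <- function(mode) {
    repeat {
      tries <<- tries + 1L
      if (tries > retry_cap) {
        stop("could not find enough distinct patch positions (retry cap hit)")
      }
      if (mode == "vessel_centered") {
        i <- sample.int(nrow(cand), 1L)
        r <- unname(cand[i, 1]) - half - 1L    # 0-based top-left
        c <- unname(cand[i, 2]) - half - 1L
        z <- unname(cand[i, 3])
      } else {
        r <- sample.int(max_r + 1L, 1L) - 1L
        c <- sample.int(max_c + 1L, 1L) - 1L
        z <- sample.int(shp[3], 1L)
      }
      p <- take(z, r, c)
      if (!is.null(p)) {
        n_got <<- n_got + 1L
        patches[[n_got]] <<- structure(
          list(image = p$image, label = p$label,
               origin = list(subject_id = vol$subject_id, z = p$z,
                             row = p$r, col = p$c),
               mode = mode),
          class = "labeled_patch")
        rows[[n_got]] <<- tibble::tibble(
          subject_id = vol$subject_id, z = p$z, row = p$r, col = p$c,
          mode = mode, label_fraction = mean(p$label))
        return(invisible(NULL))
      }
    }
  }

  if (n_vessel_centered > 0) {
    if (nrow(cand) < n_vessel_centered) stop("unreachable")  # guarded above
    for (i in seq_len(n_vessel_centered)) draw_mode("vessel_centered")
  }
  if (n_random > 0) {
    if (n_pos - n_got < n_random) {
      stop("volume has only ", n_pos, " distinct positions; cannot supply ",
           n_random, " more unique random patches")
    }
    for (i in seq_len(n_random)) draw_mode("random")
  }

  structure(
    list(patches = patches, manifest = dplyr::bind_rows(rows)),
    class = "patch_set"
  )
}

#' @export
print.patch_set <- function(x, ...) {
  m <- x$manifest
  cat("<patch_set>", length(x$patches), "patches\n")
  if (nrow(m) > 0) {
    tab <- table(m$mode)
    cat("  modes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
    cat(sprintf("  patch size: %dx%d, mean label fraction: %.4f\n",
                nrow(x$patches[[1]]$image), ncol(x$patches[[1]]$image),
                mean(m$label_fraction)))
  }
  invisible(x)
}

#' Combine several patch sets
#'
#' @param ... `patch_set` objects.
#' @return A single `patch_set`; origins must remain pairwise distinct.
#' @export
bind_patch_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !inherits(sets[[1]], "patch_set")) {
    sets <- sets[[1]]
  }
  stopifnot(all(vapply(sets, inherits, logical(1), "patch_set")))
  manifest <- dplyr::bind_rows(lapply(sets, `[[`, "manifest"))
  key <- paste(manifest$subject_id, manifest$z, manifest$row, manifest$col)
  if (anyDuplicated(key)) stop("combined patch sets contain duplicate origins")
  structure(
    list(patches = do.call(c, lapply(sets, `[[`, "patches")), manifest = manifest),
    class = "patch_set"
  )
}

#' Tidy a patch set's provenance manifest
#'
#' @param x A `patch_set`.
#' @param ... Unused.
#' @return The manifest tibble (subject_id, z, row, col, mode,
#'   label_fraction).
#' @method tidy patch_set
#' @export
tidy.patch_set <- function(x, ...) x$manifest

#' Write / read a phantom volume as NIfTI
#'
#' The intensity volume and its mask are written as two NIfTI files with
#' identical geometry (`<stem>.nii.gz` and `<stem>_mask.nii.gz`).
#'
#' @param vol A `phantom_volume`.
#' @param stem Output path stem (no extension).
#' @return `write_volume_nifti` returns the two paths invisibly;
#'   `read_volume_nifti` a `phantom_volume` (seed recorded as NA).
#' @export
write_volume_nifti <- function(vol, stem) {
  stopifnot(inherits(vol, "phantom_volume"))
  img_path <- paste0(stem, ".nii.gz")
  mask_path <- paste0(stem, "_mask.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(vol$intensity, pixdim = vol$spacing), img_path)
  RNifti::writeNifti(RNifti::asNifti(vol$mask, pixdim = vol$spacing), mask_path)
  invisible(c(image = img_path, mask = mask_path))
}

#' @rdname write_volume_nifti
#' @param subject_id Identifier to attach on read.
#' @export
read_volume_nifti <- function(stem, subject_id = basename(stem)) {
  img <- RNifti::readNifti(paste0(stem, ".nii.gz"))
  msk <- RNifti::readNifti(paste0(stem, "_mask.nii.gz"))
  structure(
    list(intensity = as.array(img), mask = array(as.integer(as.array(msk) != 0),
                                                 dim = dim(msk)),
         spacing = RNifti::pixdim(img), subject_id = subject_id, seed = NA_integer_),
    class = "phantom_volume"
  )
}

#' Persist / restore a patch set
#'
#' Images and labels go into a single RDS archive; the provenance manifest
#' is additionally written as JSON next to it (`<stem>.json`) with one
#' record per patch (origin, mode, checksum of the image bytes).
#'
#' @param ps A `patch_set`.
#' @param stem Output path stem.
#' @return `write_patch_set` the paths invisibly; `read_patch_set` the set.
#' @export
write_patch_set <- function(ps, stem) {
  stopifnot(inherits(ps, "patch_set"))
  rds <- paste0(stem, ".rds")
  saveRDS(ps, rds)
  man <- ps$manifest
  man$checksum <- vapply(ps$patches, function(p) {
    sum(p$image) + 7919 * sum(p$label)   # cheap content fingerprint
  }, numeric(1))
  jsonlite::write_json(man, paste0(stem, ".json"), digits = NA, dataframe = "rows")
  invisible(c(archive = rds, manifest = paste0(stem, ".json")))
}

#' @rdname write_patch_set
#' @export
read_patch_set <- function(stem) {
  readRDS(paste0(stem, ".rds"))
}

#' Plot a grid of labeled patches
#'
#' Shows image and label channels side by side for the first few patches.
#'
#' @param ps A `patch_set`.
#' @param n Number of patches to show (default 6).
#' @return A ggplot object.
#' @export
plot_patches <- function(ps, n = 6L) {
  stopifnot(inherits(ps, "patch_set"))
  n <- min(n, length(ps$patches))
  df <- purrr::map_dfr(seq_len(n), function(i) {
    p <- ps$patches[[i]]
    P <- nrow(p$image)
    grid <- expand.grid(row = seq_len(P), col = seq_len(P))
    dplyr::bind_rows(
      tibble::tibble(patch = i, channel = "image", row = grid$row,
                     col = grid$col, value = as.numeric(p$image)),
      tibble::tibble(patch = i, channel = "label", row = grid$row,
                     col = grid$col, value = as.numeric(p$label))
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_grid(channel ~ patch) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = NULL)
}
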