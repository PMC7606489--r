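# Synthetic liver phantoms: labeled 3D multi-channel volumes with the class
# structure background / parenchyma / viable tumor / necrosis, emulating
# three-phase dynamic contrast-enhanced T1 imaging (pre-contrast, arterial,
# venous channels).

#' Labeled multi-channel 3D volume
#'
#' Container pairing a channel-first intensity array with a voxel-wise class
#' map. Classes are coded 0 = background, 1 = parenchyma (healthy liver),
#' 2 = viable tumor, 3 = necrosis; the anomaly class used throughout the
#' package is the union \{2, 3\}.
#'
#' @param intensities numeric array of dim `(channels, X, Y, Z)`, arbitrary
#'   units.
#' @param labels integer array of dim `(X, Y, Z)` with values in 0:3.
#' @param spacing voxel size in mm per axis (length 3).
#' @param seed integer seed the volume was generated with, or `NA`.
#' @return An object of class `labeled_volume`.
#' @export
labeled_volume <- function(intensities, labels, spacing = c(1, 1, 1), seed = NA_integer_) {
  if (length(dim(intensities)) != 4L) stopf("intensities must be a 4-D (channel, x, y, z) array")
  if (length(dim(labels)) != 3L) stopf("labels must be a 3-D array")
  if (!identical(dim(intensities)[-1L], dim(labels)))
    stopf("intensities and labels disagree on the spatial grid")
  lab <- as.integer(labels)
  if (anyNA(lab) || !all(lab %in% 0:3)) stopf("labels must take values in {0,1,2,3}")
  storage.mode(labels) <- "integer"
  structure(list(intensities = intensities, labels = labels,
                 spacing = as.numeric(spacing), seed = seed),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<labeled_volume> %d channel(s), grid %s, spacing %s mm\n",
              d[1], paste(d[-1], collapse = "x"), paste(x$spacing, collapse = "x")))
  tab <- table(factor(x$labels, levels = 0:3))
  cat(sprintf("  voxels: bg %d | parenchyma %d | viable %d | necrosis %d\n",
              tab[1], tab[2], tab[3], tab[4]))
  invisible(x)
}

#' Phantom generator configuration
#'
#' Defaults emulate a cropped three-phase liver acquisition at desk scale:
#' an ellipsoidal parenchyma on dark background, 1--3 spherical viable
#' lesions, each with an optional concentric necrotic core. The arterial-like
#' channel (channel 2) carries the largest viable-vs-parenchyma contrast
#' (hyper-enhancement), the venous channel an intermediate one.
#'
#' @param shape integer length-3 grid size.
#' @param n_channels number of intensity channels.
#' @param class_means numeric matrix `(4 classes x n_channels)` of mean
#'   intensities, rows ordered background, parenchyma, viable, necrosis.
#' @param noise_sd standard deviation of additive Gaussian noise (intensity
#'   units).
#' @param n_tumors integer length-2 inclusive range of lesion counts.
#' @param tumor_radius_frac length-2 ordered range of lesion radii as a
#'   fraction of the smallest grid edge.
#' @param necrosis_prob probability that a lesion carries a necrotic core.
#' @param necrosis_radius_frac core radius as a fraction of the lesion radius.
#' @param spacing voxel size in mm per axis.
#' @param seed integer seed.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(24, 24, 24),
                           n_channels = 3,
                           class_means = default_class_means(n_channels),
                           noise_sd = 20,
                           n_tumors = c(1, 3),
                           tumor_radius_frac = c(0.08, 0.18),
                           necrosis_prob = 0.6,
                           necrosis_radius_frac = 0.5,
                           spacing = c(1, 1, 1),
                           seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stopf("shape must be 3 positive integers")
  class_means <- as.matrix(class_means)
  if (!all(dim(class_means) == c(4L, n_channels)))
    stopf("class_means must be 4 classes x %d channels", n_channels)
  if (length(tumor_radius_frac) != 2L || diff(tumor_radius_frac) < 0)
    stopf("tumor_radius_frac must be an ordered range")
  if (length(n_tumors) != 2L || n_tumors[1] > n_tumors[2] || any(n_tumors < 0))
    stopf("n_tumors must be an ordered non-negative range")
  structure(list(shape = shape, n_channels = as.integer(n_channels),
                 class_means = class_means, noise_sd = noise_sd,
                 n_tumors = as.integer(n_tumors),
                 tumor_radius_frac = tumor_radius_frac,
                 necrosis_prob = necrosis_prob,
                 necrosis_radius_frac = necrosis_radius_frac,
                 spacing = as.numeric(spacing),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Default class-mean intensity table
#'
#' Rows: background, parenchyma, viable tumor, necrosis; columns: channels in
#' acquisition order (pre-contrast, arterial-like, venous-like for the default
#' three channels). Viable tumor is strongly arterial-enhancing; necrosis is
#' hypointense and non-enhancing.
#'
#' @param n_channels number of channels (first three have distinct contrast
#'   patterns; further channels replicate the venous pattern).
#' @export
default_class_means <- function(n_channels = 3) {
  base <- rbind(background = c(5, 5, 5),
                parenchyma = c(60, 60, 65),
                viable     = c(65, 95, 80),
                necrosis   = c(45, 40, 35))
  if (n_channels <= 3) base[, seq_len(n_channels), drop = FALSE]
  else cbind(base, matrix(rep(base[, 3], n_channels - 3), nrow = 4))
}

#' Generate a labeled phantom volume
#'
#' Draws an ellipsoidal parenchyma region on background, places spherical
#' viable-tumor lesions inside it (optionally with concentric necrotic
#' cores), and renders channel intensities as class means plus i.i.d.
#' Gaussian noise. Bit-identical for identical `(config)` including its seed.
#'
#' @param config a [phantom_config()].
#' @return A [labeled_volume()].
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  shp <- config$shape
  min_r <- config$tumor_radius_frac[1] * min(shp)
  if (config$n_tumors[2] > 0 && min_r < 1)
    stopf("volume of shape %s too small to contain the minimum lesion (radius %.2f voxel)",
          paste(shp, collapse = "x"), min_r)
  with_seed(config$seed, {
    ax <- expand_grid_coords(shp)  # V x 3 voxel coordinates
    centre <- shp / 2 + runif(3, -0.05, 0.05) * shp
    semi <- runif(3, 0.33, 0.42) * shp
    u <- sweep(sweep(ax, 2, centre, "-"), 2, semi, "/")
    edist <- sqrt(rowSums(u^2))
    labels <- ifelse(edist <= 1, 1L, 0L)

    n_les <- if (config$n_tumors[2] == 0) 0L else
      sample(seq(config$n_tumors[1], config$n_tumors[2]), 1L)
    for (i in seq_len(n_les)) {
      r <- runif(1, config$tumor_radius_frac[1], config$tumor_radius_frac[2]) * min(shp)
      # lesion centre well inside the parenchyma
      inside <- which(edist <= 0.7)
      cen <- ax[inside[sample.int(length(inside), 1L)], ]
      d <- sqrt(rowSums(sweep(ax, 2, cen, "-")^2))
      labels[d <= r & labels >= 1L] <- 2L
      if (runif(1) < config$necrosis_prob) {
        rc <- config$necrosis_radius_frac * r
        labels[d <= rc & labels == 2L] <- 3L
      }
    }
    labels <- array(labels, dim = shp)

    V <- prod(shp)
    intens <- array(0, dim = c(config$n_channels, shp))
    flat <- matrix(0, nrow = config$n_channels, ncol = V)
    for (k in seq_len(config$n_channels)) {
      mu <- config$class_means[as.integer(labels) + 1L, k]
      flat[k, ] <- mu + if (config$noise_sd > 0) rnorm(V, 0, config$noise_sd) else 0
    }
    intens[] <- flat
    labeled_volume(intens, labels, spacing = config$spacing, seed = config$seed)
  })
}

# V x 3 matrix of 1-based voxel coordinates in column-major order.
expand_grid_coords <- function(shp) {
  as.matrix(expand.grid(x = seq_len(shp[1]), y = seq_len(shp[2]), z = seq_len(shp[3]),
                        KEEP.OUT.ATTRS = FALSE))
}

#' Training-time augmentation
#'
#' Applies any subset of the three stochastic augmentations used at training
#' time, in the fixed order contrast, deform, noise:
#' * `contrast` -- a random monotone (gamma-type) intensity remapping per
#'   channel; labels untouched.
#' * `deform` -- one smooth random free-form displacement field (low-
#'   resolution control grid upsampled by trilinear interpolation), applied
#'   jointly to intensities (trilinear resampling) and labels
#'   (nearest-neighbor);
#' * `noise` -- i.i.d. additive Gaussian noise on intensities only.
#'
#' @param volume a [labeled_volume()].
#' @param kinds character subset of `c("contrast", "deform", "noise")`;
#'   empty means identity.
#' @param seed integer seed.
#' @param contrast_log_gamma half-width of the uniform log-gamma draw.
#' @param deform_amplitude control-point displacement s.d. in voxels.
#' @param deform_grid control points per axis (>= 2).
#' @param noise_sd s.d. of the additive noise, intensity units.
#' @return A [labeled_volume()] on the same grid.
#' @export
augment <- function(volume, kinds, seed = 1L,
                    contrast_log_gamma = 0.3,
                    deform_amplitude = 1.5, deform_grid = 4L,
                    noise_sd = 5) {
  stopifnot(inherits(volume, "labeled_volume"))
  kinds <- unique(as.character(kinds))
  unknown <- setdiff(kinds, c("contrast", "deform", "noise"))
  if (length(unknown)) stopf("unknown augmentation kind(s): %s", paste(unknown, collapse = ", "))
  if (!length(kinds)) return(volume)
  intens <- volume$intensities
  labels <- volume$labels
  dims <- dim(labels)
  nC <- dim(intens)[1]
  with_seed(seed, {
    if ("contrast" %in% kinds) {
      for (k in seq_len(nC)) {
        ch <- intens[k, , , ]
        lo <- min(ch); hi <- max(ch)
        if (hi > lo) {
          g <- exp(runif(1, -contrast_log_gamma, contrast_log_gamma))
          intens[k, , , ] <- lo + (hi - lo) * (((ch - lo) / (hi - lo))^g)
        }
      }
    }
    if ("deform" %in% kinds) {
      disp <- random_displacement_field(dims, deform_grid, deform_amplitude)
      co <- expand_grid_coords(dims)
      src <- co + disp  # sample source coordinates
      for (k in seq_len(nC))
        intens[k, , , ] <- interp_trilinear(array(intens[k, , , ], dims), src)
      li <- clamp(round(src[, 1]), 1, dims[1])
      lj <- clamp(round(src[, 2]), 1, dims[2])
      lk <- clamp(round(src[, 3]), 1, dims[3])
      labels <- array(labels[cbind(li, lj, lk)], dims)
      storage.mode(labels) <- "integer"
    }
    if ("noise" %in% kinds && noise_sd > 0) {
      intens <- intens + array(rnorm(length(intens), 0, noise_sd), dim = dim(intens))
    }
  })
  labeled_volume(intens, labels, spacing = volume$spacing, seed = volume$seed)
}

# Random smooth displacement field: iid normal control-grid displacements
# upsampled trilinearly to the full grid. Returns V x 3 (voxel offsets).
random_displacement_field <- function(dims, grid_n, amplitude) {
  grid_n <- max(2L, as.integer(grid_n))
  ctrl <- array(rnorm(3 * grid_n^3, 0, amplitude), dim = c(grid_n, grid_n, grid_n, 3))
  co <- expand_grid_coords(dims)
  # map voxel coordinate to control-grid coordinate in [1, grid_n]
  u <- sapply(1:3, function(a) {
    if (dims[a] == 1) rep(1, nrow(co)) else (co[, a] - 1) / (dims[a] - 1) * (grid_n - 1) + 1
  })
  out <- matrix(0, nrow(co), 3)
  for (a in 1:3) out[, a] <- interp_trilinear(ctrl[, , , a], u)
  out
}

# Trilinear interpolation of a 3-D array at fractional coordinates
# (rows of `pts`, 1-based); coordinates are clamped to the volume.
interp_trilinear <- function(vol, pts) {
  dims <- dim(vol)
  px <- clamp(pts[, 1], 1, dims[1]); py <- clamp(pts[, 2], 1, dims[2]); pz <- clamp(pts[, 3], 1, dims[3])
  x0 <- clamp(floor(px), 1, max(dims[1] - 1, 1)); y0 <- clamp(floor(py), 1, max(dims[2] - 1, 1))
  z0 <- clamp(floor(pz), 1, max(dims[3] - 1, 1))
  x1 <- pmin(x0 + 1, dims[1]); y1 <- pmin(y0 + 1, dims[2]); z1 <- pmin(z0 + 1, dims[3])
  fx <- px - x0; fy <- py - y0; fz <- pz - z0
  g <- function(i, j, k) vol[cbind(i, j, k)]
  (1 - fx) * (1 - fy) * (1 - fz) * g(x0, y0, z0) +
    fx * (1 - fy) * (1 - fz) * g(x1, y0, z0) +
    (1 - fx) * fy * (1 - fz) * g(x0, y1, z0) +
    fx * fy * (1 - fz) * g(x1, y1, z0) +
    (1 - fx) * (1 - fy) * fz * g(x0, y0, z1) +
    fx * (1 - fy) * fz * g(x1, y0, z1) +
    (1 - fx) * fy * fz * g(x0, y1, z1) +
    fx * fy * fz * g(x1, y1, z1)
}

#' Sample cubic training patches from a volume
#'
#' Draws `n` cubic patches at seeded random offsets. A configurable fraction
#' of the patches is forced to contain at least one anomaly voxel (classes 2
#' or 3) by centering the patch window around a randomly chosen anomaly
#' voxel; the over-sampling counteracts the extreme class imbalance of
#' lesion-bearing volumes.
#'
#' @param volume a [labeled_volume()].
#' @param patch_edge cubic patch edge length (voxels).
#' @param n number of patches.
#' @param seed integer seed.
#' @param anomaly_fraction fraction of patches required to intersect the
#'   anomaly mask (default 0.5). If the volume has no anomaly voxels a
#'   warning is raised and plain random patches are returned.
#' @return A list of `n` [labeled_volume()] patches.
#' @export
extract_patches <- function(volume, patch_edge, n, seed = 1L, anomaly_fraction = 0.5) {
  stopifnot(inherits(volume, "labeled_volume"))
  dims <- dim(volume$labels)
  patch_edge <- as.integer(patch_edge)
  if (any(patch_edge > dims)) stopf("patch edge %d exceeds the volume dimensions", patch_edge)
  n_anom <- round(anomaly_fraction * n)
  anom_idx <- which(volume$labels >= 2L)
  if (n_anom > 0 && length(anom_idx) == 0L) {
    warning("volume contains no anomaly voxels; anomaly-fraction constraint ignored")
    n_anom <- 0L
  }
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      if (i <= n_anom) {
        v <- arrayInd(anom_idx[sample.int(length(anom_idx), 1L)], dims)
        off <- sapply(1:3, function(a) {
          lo <- max(1L, v[a] - patch_edge + 1L)
          hi <- min(dims[a] - patch_edge + 1L, v[a])
          if (hi <= lo) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
        })
      } else {
        off <- sapply(1:3, function(a)
          if (dims[a] == patch_edge) 1L else sample.int(dims[a] - patch_edge + 1L, 1L))
      }
      ix <- off[1]:(off[1] + patch_edge - 1L)
      iy <- off[2]:(off[2] + patch_edge - 1L)
      iz <- off[3]:(off[3] + patch_edge - 1L)
      labeled_volume(volume$intensities[, ix, iy, iz, drop = FALSE],
                     volume$labels[ix, iy, iz, drop = FALSE],
                     spacing = volume$spacing, seed = volume$seed)
    })
  })
}

#' Binary anomaly mask of a labeled volume
#'
#' Maps tissue classes to the binary problem analyzed throughout: viable
#' tumor and necrosis (classes 2, 3) are anomaly (1); parenchyma and
#' background (classes 0, 1) are non-anomaly (0).
#'
#' @param labels integer array or [labeled_volume()].
#' @return Integer array of 0/1 with the same spatial shape.
#' @export
anomaly_mask <- function(labels) {
  if (inherits(labels, "labeled_volume")) labels <- labels$labels
  m <- array(as.integer(labels >= 2L), dim = dim(labels))
  m
}
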