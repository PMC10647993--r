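# Paired-breath digital phantom with per-voxel ground truth.
#
# Geometry: five disjoint axis-aligned ellipsoidal lobes inside two lung
# half-masks (three stacked on the right, two on the left); the lung mask is
# their union, so the lobe labelling covers the lung exactly. Each in-mask
# voxel is assigned one of the four PRM classes at the configured per-lobe
# fractions, and paired HU values are drawn uniformly from class-specific
# intervals that keep a 1-HU guard band around the -950/-856 thresholds, so
# a zero-noise, zero-warp phantom is classified back exactly. The expiration
# can then be degraded by additive Gaussian HU noise and a smooth random
# warp whose true inverse (the alignment field) is returned.

# Inspiratory / expiratory HU sampling intervals per class (guard band of
# 1 HU around the thresholds makes zero-noise classification exact).
PHANTOM_INSP_INTERVAL <- list(emph = c(-1000, -951), fsad = c(-949, -700),
                              normal = c(-949, -700), uncat = c(-1000, -951))
PHANTOM_EXP_INTERVAL <- list(emph = c(-1000, -857), fsad = c(-1000, -857),
                             normal = c(-855, -600), uncat = c(-855, -600))

#' Configuration for the paired-breath phantom
#'
#' @param dim integer length-3 grid shape in voxels; every axis must be at
#'   least 32 so the five lobes fit disjointly.
#' @param spacing voxel spacing in mm (length 3).
#' @param class_fractions either a length-4 numeric vector (emphysema, fSAD,
#'   normal, uncategorized; applied to every lobe) or a 5 x 4 matrix with one
#'   row per lobe. Each row must be non-negative and sum to 1 within 1e-9.
#' @param noise_sd additive Gaussian HU noise standard deviation (HU, >= 0).
#' @param warp_amplitude peak displacement magnitude of the expiratory warp
#'   inside the lung, in voxels (>= 0).
#' @param warp_smoothness Gaussian smoothness scale of the random warp, in
#'   voxels.
#' @param background_hu HU value outside the lung mask (soft-tissue-like
#'   surround).
#' @param seed integer random seed.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(dim = c(64, 64, 64), spacing = c(1, 1, 1),
                           class_fractions = c(0.05, 0.15, 0.78, 0.02),
                           noise_sd = 0, warp_amplitude = 0,
                           warp_smoothness = 8, background_hu = 0, seed = 1L) {
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim < 32L))
    stop("phantom grid must be 3-D with every axis >= 32 voxels")
  if (is.null(nrow(class_fractions)))
    class_fractions <- matrix(class_fractions, nrow = 5, ncol = 4, byrow = TRUE)
  class_fractions <- as.matrix(class_fractions)
  if (nrow(class_fractions) != 5L || ncol(class_fractions) != 4L)
    stop("class_fractions must be a length-4 vector or a 5 x 4 matrix")
  if (any(class_fractions < 0) || any(abs(rowSums(class_fractions) - 1) > 1e-9))
    stop("class fractions must be non-negative and sum to 1 per lobe")
  stopifnot(noise_sd >= 0, warp_amplitude >= 0, warp_smoothness > 0)
  structure(list(dim = dim, spacing = as.numeric(spacing),
                 class_fractions = class_fractions, noise_sd = noise_sd,
                 warp_amplitude = warp_amplitude,
                 warp_smoothness = warp_smoothness,
                 background_hu = background_hu, seed = as.integer(seed)),
            class = "phantom_config")
}

# Integer lobe-label volume: ellipsoidal lobes 1-3 (right lung) stacked along
# axis 3, lobes 4-5 (left lung) likewise; disjoint by construction.
phantom_lobe_mask <- function(d) {
  g <- index_grids(d)
  lobe <- array(0L, d)
  ellipsoid <- function(cx, cy, cz, rx, ry, rz)
    ((g$i - cx) / rx)^2 + ((g$j - cy) / ry)^2 + ((g$k - cz) / rz)^2 <= 1
  cy <- 0.5 * d[2]
  rx <- 0.16 * d[1]; ry <- 0.28 * d[2]
  # right lung (lobes 1 upper, 2 middle, 3 lower)
  for (l in 1:3) {
    cz <- (0.25 * l) * d[3]
    lobe[ellipsoid(0.28 * d[1], cy, cz, rx, ry, 0.11 * d[3])] <- l
  }
  # left lung (4 upper, 5 lower)
  lobe[ellipsoid(0.72 * d[1], cy, 0.35 * d[3], rx, ry, 0.14 * d[3])] <- 4L
  lobe[ellipsoid(0.72 * d[1], cy, 0.68 * d[3], rx, ry, 0.14 * d[3])] <- 5L
  lobe
}

# Smooth random alignment field, tapered to zero at the lung-mask boundary,
# scaled so the peak in-mask magnitude equals `amplitude`.
random_alignment_field <- function(mask, amplitude, smoothness) {
  d <- dim(mask)
  if (amplitude <= 0)
    return(displacement_field(array(0, d), array(0, d), array(0, d)))
  s <- smooth_volume(array(as.numeric(mask), d), 4)
  taper <- pmax(0, (s - 0.5) / 0.5)
  comps <- lapply(1:3, function(i) smooth_volume(array(stats::rnorm(prod(d)), d), smoothness) * taper)
  mag <- sqrt(comps[[1]]^2 + comps[[2]]^2 + comps[[3]]^2)
  peak <- max(mag[mask])
  if (peak == 0) stop("degenerate random field; increase grid size")
  sc <- amplitude / peak
  displacement_field(comps[[1]] * sc, comps[[2]] * sc, comps[[3]] * sc)
}

#' Generate a paired-breath phantom with ground truth
#'
#' Builds the lobe geometry, assigns every in-mask voxel a PRM class at the
#' configured per-lobe fractions, draws paired HU values from the class
#' intervals, adds HU noise, and warps the expiration (and nothing else) by
#' a smooth random displacement. The returned truth contains the label map,
#' the per-lobe class-assignment counts, the pre-warp expiration, and the
#' alignment field that maps the warped expiration back onto the
#' inspiratory grid (the inverse of the applied warp).
#'
#' @param config a [phantom_config()].
#' @return list with elements `study` (a [paired_study()]) and `truth`
#'   (list: `label_map`, `class_counts` 5 x 4 matrix, `exp_prewarp`,
#'   `alignment_field`, `config`).
#' @export
generate_phantom_pair <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  d <- config$dim
  lobe <- phantom_lobe_mask(d)
  mask <- lobe > 0L

  # per-voxel class assignment at the lobe's target fractions
  lab <- array(0L, d)
  counts <- matrix(0L, 5, 4, dimnames = list(paste0("lobe", 1:5),
                                             c("emph", "fsad", "normal", "uncat")))
  for (l in 1:5) {
    idx <- which(lobe == l)
    cls <- sample.int(4L, length(idx), replace = TRUE, prob = config$class_fractions[l, ])
    lab[idx] <- cls
    counts[l, ] <- tabulate(cls, nbins = 4L)
  }

  insp <- array(config$background_hu, d)
  exp0 <- array(config$background_hu, d)
  for (c in 1:4) {
    idx <- which(lab == c)
    if (!length(idx)) next
    ii <- PHANTOM_INSP_INTERVAL[[c]]; ee <- PHANTOM_EXP_INTERVAL[[c]]
    insp[idx] <- stats::runif(length(idx), ii[1], ii[2])
    exp0[idx] <- stats::runif(length(idx), ee[1], ee[2])
  }
  if (config$noise_sd > 0) {
    insp <- insp + array(stats::rnorm(prod(d), 0, config$noise_sd), d)
    exp0 <- exp0 + array(stats::rnorm(prod(d), 0, config$noise_sd), d)
  }

  align <- random_alignment_field(mask, config$warp_amplitude, config$warp_smoothness)
  if (config$warp_amplitude > 0) {
    warp <- invert_displacement_field(align)
    exp_obs <- warp_volume(exp0, warp)
  } else {
    exp_obs <- exp0
  }

  label_map <- lab
  attr(label_map, "spacing") <- config$spacing
  class(label_map) <- c("prm_label_map", class(label_map))

  list(study = paired_study(insp, exp_obs, mask, lobe, config$spacing),
       truth = list(label_map = label_map, class_counts = counts,
                    exp_prewarp = with_spacing(exp0, config$spacing),
                    alignment_field = align, config = config))
}

#' Write a phantom to disk as NIfTI volumes
#'
#' Writes `insp.nii.gz`, `exp.nii.gz`, `lung_mask.nii.gz`,
#' `lobe_mask.nii.gz` (labels 1-5), `prm_truth.nii.gz` and the alignment
#' field `alignment_field.nii.gz` (4-D, three displacement components in
#' voxel units) under `dir`.
#'
#' @param phantom result of [generate_phantom_pair()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  st <- phantom$study
  sp <- st$spacing
  write_volume_nifti(st$insp, file.path(dir, "insp.nii.gz"))
  write_volume_nifti(st$exp, file.path(dir, "exp.nii.gz"))
  write_volume_nifti(with_spacing(st$lung_mask + 0, sp), file.path(dir, "lung_mask.nii.gz"))
  write_volume_nifti(with_spacing(st$lobe_mask + 0, sp), file.path(dir, "lobe_mask.nii.gz"))
  write_volume_nifti(with_spacing(unclass(phantom$truth$label_map) + 0, sp),
                     file.path(dir, "prm_truth.nii.gz"))
  write_displacement_field(phantom$truth$alignment_field,
                           file.path(dir, "alignment_field.nii.gz"), sp)
  invisible(dir)
}
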