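# ---- 3-D array primitives shared by the phantom generator, the deformable
# ---- registration, and the PRM aggregation. Volumes are plain numeric 3-D
# ---- arrays with a "spacing" attribute (mm per voxel along each axis).

#' Attach voxel spacing to a 3-D volume
#'
#' @param x numeric 3-D array.
#' @param spacing numeric length-3, mm per voxel along each array axis.
#' @return `x` with a `spacing` attribute.
#' @export
with_spacing <- function(x, spacing) {
  stopifnot(length(dim(x)) == 3L, length(spacing) == 3L, all(spacing > 0))
  attr(x, "spacing") <- as.numeric(spacing)
  x
}

#' Voxel spacing of a volume (mm), defaulting to isotropic 1 mm
#' @param x a 3-D array, possibly carrying a `spacing` attribute.
#' @return numeric length-3.
#' @export
voxel_spacing <- function(x) {
  sp <- attr(x, "spacing")
  if (is.null(sp)) rep(1, 3) else sp
}

#' Volume of one voxel in millilitres
#' @param spacing numeric length-3 voxel spacing in mm.
#' @return scalar, mL (1 mL = 1000 mm^3).
#' @export
voxel_volume_ml <- function(spacing) prod(spacing) / 1000

# Row-normalized discrete Gaussian convolution matrix for one axis.
# Renormalization at the ends gives reflecting-like boundary behaviour.
gaussian_kernel_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  K <- outer(seq_len(n), seq_len(n), function(i, j) stats::dnorm(j - i, sd = sigma))
  K / rowSums(K)
}

smooth_along_axis <- function(a, K, axis) {
  d <- dim(a)
  if (axis == 1L) {
    array(K %*% matrix(a, d[1], d[2] * d[3]), d)
  } else if (axis == 2L) {
    p <- aperm(a, c(2, 1, 3))
    p <- array(K %*% matrix(p, d[2], d[1] * d[3]), c(d[2], d[1], d[3]))
    aperm(p, c(2, 1, 3))
  } else {
    p <- aperm(a, c(3, 1, 2))
    p <- array(K %*% matrix(p, d[3], d[1] * d[2]), c(d[3], d[1], d[2]))
    aperm(p, c(2, 3, 1))
  }
}

#' Separable Gaussian smoothing of a 3-D array
#'
#' @param a numeric 3-D array.
#' @param sigma standard deviation in voxels; `0` returns `a` unchanged.
#' @return smoothed array of the same dimensions.
#' @export
smooth_volume <- function(a, sigma) {
  if (sigma <= 0) return(a)
  d <- dim(a)
  for (ax in 1:3) a <- smooth_along_axis(a, gaussian_kernel_matrix(d[ax], sigma), ax)
  a
}

# Index grids (1-based voxel coordinates) for a given dim; memo-free, cheap.
index_grids <- function(d) {
  list(
    i = array(rep(seq_len(d[1]), times = d[2] * d[3]), d),
    j = array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d),
    k = array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
  )
}

#' Trilinear interpolation of a volume at arbitrary voxel coordinates
#'
#' Coordinates are 1-based voxel indices; samples are clamped to the volume
#' boundary. Used by warping, field inversion and registration.
#'
#' @param vol numeric 3-D array.
#' @param x,y,z numeric vectors of equal length, voxel coordinates.
#' @return numeric vector of interpolated values.
#' @export
interp_trilinear <- function(vol, x, y, z) {
  d <- dim(vol)
  x <- pmin(pmax(x, 1), d[1]); y <- pmin(pmax(y, 1), d[2]); z <- pmin(pmax(z, 1), d[3])
  x0 <- pmin(floor(x), d[1] - 1); y0 <- pmin(floor(y), d[2] - 1); z0 <- pmin(floor(z), d[3] - 1)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  i000 <- x0 + (y0 - 1) * d[1] + (z0 - 1) * d[1] * d[2]
  i100 <- i000 + 1
  i010 <- i000 + d[1]
  i110 <- i010 + 1
  i001 <- i000 + d[1] * d[2]
  i101 <- i001 + 1
  i011 <- i001 + d[1]
  i111 <- i011 + 1
  (vol[i000] * (1 - fx) + vol[i100] * fx) * (1 - fy) * (1 - fz) +
  (vol[i010] * (1 - fx) + vol[i110] * fx) * fy * (1 - fz) +
  (vol[i001] * (1 - fx) + vol[i101] * fx) * (1 - fy) * fz +
  (vol[i011] * (1 - fx) + vol[i111] * fx) * fy * fz
}

# Central-difference gradient (voxel units); one-sided zeros at the faces.
gradient_volume <- function(a) {
  d <- dim(a)
  gx <- array(0, d); gy <- array(0, d); gz <- array(0, d)
  gx[2:(d[1] - 1), , ] <- (a[3:d[1], , ] - a[1:(d[1] - 2), , ]) / 2
  gy[, 2:(d[2] - 1), ] <- (a[, 3:d[2], ] - a[, 1:(d[2] - 2), ]) / 2
  gz[, , 2:(d[3] - 1)] <- (a[, , 3:d[3]] - a[, , 1:(d[3] - 2)]) / 2
  list(gx, gy, gz)
}

# ---- Paired study container -------------------------------------------------

#' Construct a paired inspiratory/expiratory study
#'
#' Bundles the two breath-hold volumes with the lung and lobe masks on the
#' inspiratory grid. Lobe labels are integer-coded 1-5: 1 = right upper,
#' 2 = right middle, 3 = right lower, 4 = left upper, 5 = left lower; the
#' right lung is lobes \{1,2,3\} and the left lung lobes \{4,5\}.
#'
#' @param insp,exp numeric 3-D HU arrays on the same grid.
#' @param lung_mask logical/0-1 array, the lung region.
#' @param lobe_mask integer array with labels 0 (outside) and 1-5.
#' @param spacing voxel spacing in mm (length 3).
#' @param exp_registered optional expiration already resampled onto the
#'   inspiratory grid (e.g. from an external registration tool).
#' @return an object of class `paired_study`.
#' @export
paired_study <- function(insp, exp, lung_mask, lobe_mask, spacing = c(1, 1, 1),
                         exp_registered = NULL) {
  d <- dim(insp)
  stopifnot(length(d) == 3L)
  if (!identical(dim(exp), d) || !identical(dim(lung_mask), d) || !identical(dim(lobe_mask), d))
    stop("all volumes of a paired study must share the inspiratory grid dimensions")
  if (!is.null(exp_registered) && !identical(dim(exp_registered), d))
    stop("exp_registered must share the inspiratory grid dimensions")
  structure(
    list(insp = with_spacing(insp, spacing), exp = with_spacing(exp, spacing),
         lung_mask = array(as.logical(lung_mask), d),
         lobe_mask = array(as.integer(lobe_mask), d),
         spacing = as.numeric(spacing), exp_registered = exp_registered),
    class = "paired_study")
}

#' @export
print.paired_study <- function(x, ...) {
  d <- dim(x$insp)
  cat(sprintf("Paired inspiratory/expiratory study: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x ")))
  cat(sprintf("  lung voxels: %d (%.1f mL); expiration registered: %s\n",
              sum(x$lung_mask), sum(x$lung_mask) * voxel_volume_ml(x$spacing),
              if (is.null(x$exp_registered)) "no" else "yes"))
  invisible(x)
}

# ---- NIfTI I/O --------------------------------------------------------------

#' Write a volume to NIfTI
#' @param x 3-D array with optional `spacing` attribute.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(x, path) {
  img <- RNifti::asNifti(array(as.numeric(x), dim(x)))
  RNifti::pixdim(img) <- voxel_spacing(x)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI as a spacing-tagged array
#' @param path NIfTI file path.
#' @return 3-D array with a `spacing` attribute.
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  with_spacing(array(as.numeric(img), dim(img)[1:3]), RNifti::pixdim(img)[1:3])
}
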