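# Parametric response mapping: joint thresholding of co-registered
# inspiratory/expiratory HU against -950 HU (inspiration) and -856 HU
# (expiration). The four categories partition the HU plane:
#   emphysema     insp <= -950 & exp <= -856   (label 1)
#   fSAD          insp >  -950 & exp <= -856   (label 2)
#   normal        insp >  -950 & exp >  -856   (label 3)
#   uncategorized insp <= -950 & exp >  -856   (label 4)
# Boundary voxels (exactly -950 / -856) follow the half-plane convention
# insp <= -950 and exp <= -856; they are measure-zero in real data.

PRM_INSP_THRESHOLD <- -950
PRM_EXP_THRESHOLD <- -856

#' PRM class labels
#'
#' Integer coding of the parametric-response-mapping classes used in label
#' maps: 0 outside the lung mask, then emphysema, fSAD (functional
#' small-airways disease), normal lung, and uncategorized tissue.
#' @return named integer vector.
#' @export
prm_classes <- function() {
  c(outside = 0L, emph = 1L, fsad = 2L, normal = 3L, uncat = 4L)
}

#' Classify voxels into PRM categories
#'
#' Vectorized joint thresholding of paired HU values. Emphysema is
#' inspiratory HU \eqn{\le -950} with expiratory HU \eqn{\le -856}; fSAD is
#' inspiratory \eqn{> -950} with expiratory \eqn{\le -856} (air trapping
#' without parenchymal destruction); normal lung is above both thresholds;
#' uncategorized tissue is at or below \eqn{-950} at inspiration but above
#' \eqn{-856} at expiration.
#'
#' @param insp_hu,exp_hu numeric vectors of paired HU values.
#' @return integer vector of labels in 1-4 (see [prm_classes()]).
#' @export
classify_prm <- function(insp_hu, exp_hu) {
  if (length(insp_hu) != length(exp_hu))
    stop("inspiratory and expiratory HU vectors must have equal length")
  if (length(insp_hu) && (anyNA(insp_hu) || anyNA(exp_hu) ||
      any(!is.finite(insp_hu)) || any(!is.finite(exp_hu))))
    stop("non-finite HU values cannot be classified")
  low_insp <- insp_hu <= PRM_INSP_THRESHOLD
  low_exp <- exp_hu <= PRM_EXP_THRESHOLD
  ifelse(low_exp, ifelse(low_insp, 1L, 2L), ifelse(low_insp, 4L, 3L))
}

#' Compute a PRM label map from co-registered volumes
#'
#' Applies [classify_prm()] inside the lung mask and writes label 0 outside.
#' An optional inspiratory HU validity window excludes voxels outside
#' `[-1000, -250]` from the mask (airway lumen / dense tissue guard); it is
#' off by default, which reproduces the plain threshold rule.
#'
#' @param insp inspiratory HU volume.
#' @param exp_registered expiratory HU volume resampled onto the inspiratory
#'   grid.
#' @param lung_mask logical volume on the same grid.
#' @param hu_validity_window logical; drop voxels with inspiratory HU outside
#'   `[-1000, -250]`.
#' @return integer 3-D array of class `prm_label_map` with the study spacing
#'   attached.
#' @export
compute_prm_map <- function(insp, exp_registered, lung_mask,
                            hu_validity_window = FALSE) {
  d <- dim(insp)
  if (!identical(dim(exp_registered), d) || !identical(dim(lung_mask), d))
    stop("inspiratory volume, registered expiration and lung mask must share one grid")
  mask <- array(as.logical(lung_mask), d)
  if (hu_validity_window)
    mask <- mask & insp >= -1000 & insp <= -250
  out <- array(0L, d)
  if (any(mask))
    out[mask] <- classify_prm(insp[mask], exp_registered[mask])
  attr(out, "spacing") <- voxel_spacing(insp)
  class(out) <- c("prm_label_map", class(out))
  out
}

# ---- regional aggregation ---------------------------------------------------

#' Region and quantity layout of the 72 PRM parameters
#'
#' Nine quantities (region lung volume LV in mL; the four class volumes in
#' mL; the four class percentages of LV) over eight regions (whole lung,
#' left lung, right lung, and the five lobes) give the 72-parameter vector.
#' Names follow `prm_<region>_<quantity>`.
#'
#' @return character vector of the 72 parameter names in canonical order.
#' @export
prm_parameter_names <- function() {
  q <- c("lv_ml", "emph_ml", "fsad_ml", "normal_ml", "uncat_ml",
         "emph_pct", "fsad_pct", "normal_pct", "uncat_pct")
  as.vector(vapply(prm_regions(), function(r) paste0("prm_", r, "_", q),
                   character(length(q))))
}

#' Names of the eight PRM aggregation regions, in canonical order
#' @return character vector: whole, left, right, rul, rml, rll, lul, lll.
#' @export
prm_regions <- function() c("whole", "left", "right", "rul", "rml", "rll", "lul", "lll")

# lobe label sets per region; lobes 1-3 right, 4-5 left
region_lobes <- function() {
  list(whole = 1:5, left = 4:5, right = 1:3,
       rul = 1L, rml = 2L, rll = 3L, lul = 4L, lll = 5L)
}

#' Aggregate a PRM label map into the 72 regional parameters
#'
#' Counts voxels per class per region and converts to volumes (mL, voxel
#' count times voxel volume) and percentages of the region lung volume.
#' Regions with zero lung volume report all percentages as 0 and are listed
#' in the `empty_regions` attribute. Lung-mask voxels not covered by any
#' lobe label contribute to the whole-lung region only; a warning reports
#' their count.
#'
#' @param label_map integer PRM label map (from [compute_prm_map()] or a
#'   phantom's ground truth).
#' @param lobe_mask integer volume with lobe labels 1-5 (0 elsewhere).
#' @param spacing voxel spacing in mm; defaults to the map's own.
#' @return named numeric vector of length 72 (see [prm_parameter_names()]),
#'   class `prm_parameters`.
#' @export
aggregate_prm_regions <- function(label_map, lobe_mask, spacing = NULL) {
  d <- dim(label_map)
  if (!identical(dim(lobe_mask), d))
    stop("lobe mask must share the label map grid")
  if (is.null(spacing)) spacing <- voxel_spacing(label_map)
  vox_ml <- voxel_volume_ml(spacing)

  lab <- as.integer(label_map)
  lobe <- as.integer(lobe_mask)
  in_lung <- lab > 0L
  uncovered <- sum(in_lung & lobe == 0L)
  if (uncovered > 0)
    warning(sprintf("%d lung voxels carry no lobe label; counted in whole lung only", uncovered))

  # class counts per lobe (rows: lobe 0..5, cols: class 1..4)
  counts <- matrix(0, nrow = 6, ncol = 4)
  tab <- table(factor(lobe[in_lung], levels = 0:5), factor(lab[in_lung], levels = 1:4))
  counts[] <- as.numeric(tab)

  regions <- region_lobes()
  out <- numeric(0)
  empty <- character(0)
  for (rn in names(regions)) {
    cls <- if (rn == "whole") colSums(counts) else
      colSums(counts[regions[[rn]] + 1, , drop = FALSE])
    lv <- sum(cls)
    vols <- cls * vox_ml
    if (lv > 0) pct <- cls / lv * 100 else { pct <- rep(0, 4); empty <- c(empty, rn) }
    out <- c(out, lv * vox_ml, vols, pct)
  }
  names(out) <- prm_parameter_names()
  structure(out, empty_regions = empty, class = c("prm_parameters", "numeric"))
}

#' @export
print.prm_parameters <- function(x, ...) {
  cat("72 PRM parameters (mL / % of region LV)\n")
  m <- matrix(unclass(x), nrow = 9,
              dimnames = list(c("LV", "Emph", "fSAD", "Normal", "Uncat",
                                "Emph%", "fSAD%", "Normal%", "Uncat%"),
                              prm_regions()))
  print(round(m, 2), ...)
  ez <- attr(x, "empty_regions")
  if (length(ez)) cat("regions with zero lung volume:", paste(ez, collapse = ", "), "\n")
  invisible(x)
}

#' Full PRM measurement of a paired study
#'
#' Convenience wrapper: classifies the registered expiration against the
#' inspiration and aggregates the regional parameters.
#'
#' @param study a [paired_study()]; `exp_registered` must be present (use
#'   [register_exp_to_insp()] or [apply_displacement_field()] first), unless
#'   the raw expiration is already on the inspiratory grid
#'   (`use_raw_exp = TRUE`).
#' @param use_raw_exp treat `study$exp` as already aligned.
#' @param hu_validity_window see [compute_prm_map()].
#' @return list with elements `label_map` and `parameters`.
#' @export
measure_prm <- function(study, use_raw_exp = is.null(study$exp_registered),
                        hu_validity_window = FALSE) {
  stopifnot(inherits(study, "paired_study"))
  expv <- if (use_raw_exp) study$exp else study$exp_registered
  if (is.null(expv)) stop("study has no registered expiration")
  map <- compute_prm_map(study$insp, expv, study$lung_mask, hu_validity_window)
  list(label_map = map,
       parameters = aggregate_prm_regions(map, study$lobe_mask, study$spacing))
}
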