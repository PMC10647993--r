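# Synthetic screening cohort. Each subject carries the 72 regional PRM
# parameters plus age, sex, height and weight, and spirometry generated by
# an explicit linear model in the whole-lung fSAD% and emphysema%:
#
#   FEV1/FVC = a0 + a_f * fSAD% + a_e * Emph% + N(0, sd_ff)
#   FEV1%    = b0 + b_f * fSAD% + b_e * Emph% + N(0, sd_fp)
#
# with negative slopes (more small-airways disease and emphysema mean worse
# airflow). Regional values are generated per lobe and aggregated exactly
# the way the image pipeline aggregates them, so whole-lung percentages are
# the lobe-volume-weighted values and the four classes sum to 100% in every
# region. The default coefficients were fixed once so that staging the
# noiseless spirometry yields roughly 60% normal / 30% high-risk / 10% COPD,
# the class balance typical of a community screening population.

#' Feature columns used by the regression models
#' @return character vector of the 76 feature names (72 PRM + 4 clinical).
#' @export
prm_feature_columns <- function() c(prm_parameter_names(), "age", "sex", "height", "weight")

#' Configuration for the synthetic cohort generator
#'
#' @param n number of subjects (> 0).
#' @param coef_fev1_fvc,coef_fev1_pct named numeric vectors
#'   `c(intercept, fsad, emph)`: intercept in fraction units and slopes per
#'   percentage point of whole-lung PRM fSAD% / Emph%.
#' @param noise_sd_fev1_fvc,noise_sd_fev1_pct Gaussian noise SDs of the two
#'   outcomes (fraction units).
#' @param fsad_shape,fsad_scale Gamma parameters of the per-subject
#'   whole-lung fSAD% severity distribution.
#' @param emph_fsad_slope,emph_shape,emph_scale emphysema% model: a linear
#'   share of fSAD% plus an independent Gamma component.
#' @param uncat_shape,uncat_scale Gamma parameters of uncategorized%.
#' @param lobe_jitter_sd log-normal SD of the per-lobe deviation around the
#'   subject-level class percentages.
#' @param age_mean,age_sd,age_range age marginal (years; rounded, clipped).
#' @param p_male probability of male sex (coded 1; female 0).
#' @param height_mean_male,height_mean_female,height_sd height marginal (cm).
#' @param weight_mean,weight_sd weight marginal (kg).
#' @param lv_mean,lv_sd whole-lung volume marginal (mL).
#' @param seed integer random seed.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n = 615L,
                          coef_fev1_fvc = c(intercept = 0.87, fsad = -0.0045, emph = -0.012),
                          coef_fev1_pct = c(intercept = 1.14, fsad = -0.0123, emph = -0.010),
                          noise_sd_fev1_fvc = 0.03, noise_sd_fev1_pct = 0.06,
                          fsad_shape = 1.8, fsad_scale = 7,
                          emph_fsad_slope = 0.12, emph_shape = 0.8, emph_scale = 1.5,
                          uncat_shape = 1.5, uncat_scale = 1.2,
                          lobe_jitter_sd = 0.25,
                          age_mean = 67, age_sd = 5, age_range = c(40, 74),
                          p_male = 0.47,
                          height_mean_male = 168, height_mean_female = 157, height_sd = 6,
                          weight_mean = 65, weight_sd = 10,
                          lv_mean = 4400, lv_sd = 900, seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n <= 0L) stop("cohort size n must be a positive integer")
  stopifnot(noise_sd_fev1_fvc >= 0, noise_sd_fev1_pct >= 0,
            length(coef_fev1_fvc) == 3L, length(coef_fev1_pct) == 3L)
  structure(as.list(environment()), class = "cohort_config")
}

# per-subject lobe-level class percentages consistent with the aggregation
# rule; returns list(features = named 72-vector data, fsad_wl, emph_wl)
cohort_regional_features <- function(cfg, n) {
  lobe_base <- c(0.20, 0.11, 0.23, 0.26, 0.20)
  # subject-level severities (percent of region volume)
  fsad_s <- pmin(stats::rgamma(n, shape = cfg$fsad_shape, scale = cfg$fsad_scale), 70)
  emph_s <- pmin(cfg$emph_fsad_slope * fsad_s +
                   stats::rgamma(n, shape = cfg$emph_shape, scale = cfg$emph_scale), 40)
  uncat_s <- pmin(stats::rgamma(n, shape = cfg$uncat_shape, scale = cfg$uncat_scale), 10)
  lv_total <- pmin(pmax(stats::rnorm(n, cfg$lv_mean, cfg$lv_sd), 2500), 8000)

  # per-lobe volumes: Dirichlet jitter around typical lobar shares
  galpha <- matrix(stats::rgamma(n * 5, shape = rep(lobe_base * 60, each = n)), n, 5)
  lv_lobe <- galpha / rowSums(galpha) * lv_total

  # per-lobe class percentages: log-normal jitter, capped so normal% > 0
  jit <- function() matrix(exp(stats::rnorm(n * 5, 0, cfg$lobe_jitter_sd)), n, 5)
  fsad_l <- fsad_s * jit(); emph_l <- emph_s * jit(); uncat_l <- uncat_s * jit()
  tot <- fsad_l + emph_l + uncat_l
  over <- tot > 95
  if (any(over)) {
    sc <- 95 / tot
    fsad_l[over] <- fsad_l[over] * sc[over]
    emph_l[over] <- emph_l[over] * sc[over]
    uncat_l[over] <- uncat_l[over] * sc[over]
  }
  normal_l <- 100 - fsad_l - emph_l - uncat_l

  # class volumes per lobe (mL), then regional aggregation
  vol <- list(emph = emph_l, fsad = fsad_l, normal = normal_l, uncat = uncat_l)
  vol <- lapply(vol, function(p) p / 100 * lv_lobe)
  regions <- region_lobes()
  feats <- matrix(NA_real_, n, 72, dimnames = list(NULL, prm_parameter_names()))
  for (rn in names(regions)) {
    lobes <- regions[[rn]]
    lv_r <- rowSums(lv_lobe[, lobes, drop = FALSE])
    v <- lapply(vol, function(m) rowSums(m[, lobes, drop = FALSE]))
    feats[, paste0("prm_", rn, "_lv_ml")] <- lv_r
    for (cl in names(v)) {
      feats[, paste0("prm_", rn, "_", cl, "_ml")] <- v[[cl]]
      feats[, paste0("prm_", rn, "_", cl, "_pct")] <- v[[cl]] / lv_r * 100
    }
  }
  list(features = feats,
       fsad_wl = feats[, "prm_whole_fsad_pct"],
       emph_wl = feats[, "prm_whole_emph_pct"])
}

#' Generate a synthetic screening cohort
#'
#' Draws regional PRM parameters and clinical covariates, generates
#' spirometry from the configured linear model, and stages each subject
#' from the noiseless spirometry (the generator's ground-truth label). The
#' emitted `fev1_fvc` / `fev1_pct` columns carry the measurement noise and
#' are clipped to (0, 1.2] and (0, 1.6] respectively.
#'
#' @param config a [cohort_config()].
#' @return data.frame with the 72 PRM columns, `age`, `sex`, `height`,
#'   `weight`, `fev1_fvc`, `fev1_pct`, `group`; the noiseless spirometry and
#'   ground-truth GOLD stage are kept in the `truth` attribute.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n

  reg <- cohort_regional_features(config, n)

  age <- pmin(pmax(round(stats::rnorm(n, config$age_mean, config$age_sd)),
                   config$age_range[1]), config$age_range[2])
  sex <- stats::rbinom(n, 1, config$p_male)
  height <- stats::rnorm(n, ifelse(sex == 1, config$height_mean_male,
                                   config$height_mean_female), config$height_sd)
  weight <- pmin(pmax(stats::rnorm(n, config$weight_mean, config$weight_sd), 40), 120)

  a <- config$coef_fev1_fvc; b <- config$coef_fev1_pct
  ff_true <- a[[1]] + a[[2]] * reg$fsad_wl + a[[3]] * reg$emph_wl
  fp_true <- b[[1]] + b[[2]] * reg$fsad_wl + b[[3]] * reg$emph_wl
  ff_true <- pmin(pmax(ff_true, 0.05), 1.2)
  fp_true <- pmin(pmax(fp_true, 0.05), 1.6)
  ff <- pmin(pmax(ff_true + stats::rnorm(n, 0, config$noise_sd_fev1_fvc), 0.05), 1.2)
  fp <- pmin(pmax(fp_true + stats::rnorm(n, 0, config$noise_sd_fev1_pct), 0.05), 1.6)

  truth_cl <- classify_group(ff_true, fp_true)
  out <- data.frame(reg$features, age = age, sex = sex, height = height,
                    weight = weight, fev1_fvc = ff, fev1_pct = fp,
                    group = truth_cl$group)
  attr(out, "truth") <- data.frame(fev1_fvc_true = ff_true, fev1_pct_true = fp_true,
                                   gold_true = truth_cl$gold)
  attr(out, "config") <- config
  out
}

#' Write a cohort table to CSV in the canonical column order
#' @param cohort data.frame from [generate_cohort()] (or compatible).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  cols <- c(prm_feature_columns(), "fev1_fvc", "fev1_pct", "group")
  missing <- setdiff(cols, names(cohort))
  if (length(missing))
    stop("cohort is missing columns: ", paste(missing, collapse = ", "))
  utils::write.csv(cohort[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Spirometry columns recorded on the percent scale (values above 2) are
#' detected and rescaled to fractions, with a message; this guards against
#' the two unit conventions in circulation for FEV1% predicted.
#'
#' @param path CSV path with the canonical columns.
#' @return data.frame in fraction units.
#' @export
read_cohort_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("fev1_fvc", "fev1_pct")) {
    if (col %in% names(x) && stats::median(x[[col]], na.rm = TRUE) > 2) {
      message(sprintf("column %s appears to be on the percent scale; dividing by 100", col))
      x[[col]] <- x[[col]] / 100
    }
  }
  if ("group" %in% names(x))
    x$group <- factor(x$group, levels = c("normal", "high_risk", "copd"))
  x
}
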