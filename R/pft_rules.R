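# Rule-based staging from spirometry. All comparisons are in fraction units
# (FEV1/FVC as a ratio, FEV1% predicted as a fraction of predicted).
#
#   COPD      : FEV1/FVC < 0.7, severity by GOLD stage of FEV1%
#   normal    : FEV1/FVC >= 0.7 and FEV1% >= 0.95
#   high-risk : FEV1/FVC >= 0.7 and FEV1% < 0.95
#
# Two gaps in the verbal definitions are resolved deterministically:
# FEV1/FVC exactly 0.7 is non-COPD (GOLD's obstruction criterion is a strict
# "<"), and among non-COPD every FEV1% below 0.95 is high-risk, including
# values below the nominal 0.80 lower band edge -- predicted spirometry can
# land there and is treated as (at least) high-risk.

#' GOLD severity stage from FEV1% predicted
#'
#' Applies the GOLD cutoffs for subjects with established airflow
#' obstruction (FEV1/FVC < 0.7): stage I for FEV1% \eqn{\ge} 0.80, II for
#' [0.50, 0.80), III for [0.30, 0.50), IV below 0.30.
#'
#' @param fev1_pct numeric vector, FEV1% predicted as a fraction.
#' @return character vector in `c("I","II","III","IV")`.
#' @export
gold_stage <- function(fev1_pct) {
  stopifnot(all(is.finite(fev1_pct)))
  cut(fev1_pct, breaks = c(-Inf, 0.30, 0.50, 0.80, Inf),
      labels = c("IV", "III", "II", "I"), right = FALSE) |> as.character()
}

#' Stage subjects as normal / high-risk / COPD from spirometry
#'
#' Vectorized staging rule; works identically on measured values and on
#' model predictions (the prediction-based confusion matrices are built by
#' feeding predicted spirometry through this same rule).
#'
#' @param fev1_fvc numeric vector, FEV1/FVC ratio (fraction, in (0, 1.2]).
#' @param fev1_pct numeric vector, FEV1% predicted (fraction, in (0, 1.6]).
#' @return data.frame with columns `group` (factor: normal, high_risk, copd)
#'   and `gold` (factor: none, I, II, III, IV; `none` iff non-COPD).
#' @export
classify_group <- function(fev1_fvc, fev1_pct) {
  if (length(fev1_fvc) != length(fev1_pct))
    stop("fev1_fvc and fev1_pct must have equal length")
  stopifnot(all(is.finite(fev1_fvc)), all(is.finite(fev1_pct)),
            all(fev1_fvc > 0), all(fev1_pct > 0))
  copd <- fev1_fvc < 0.7
  group <- ifelse(copd, "copd", ifelse(fev1_pct >= 0.95, "normal", "high_risk"))
  gold <- ifelse(copd, gold_stage(fev1_pct), "none")
  data.frame(group = factor(group, levels = c("normal", "high_risk", "copd")),
             gold = factor(gold, levels = c("none", "I", "II", "III", "IV")))
}

#' Stage a cohort table from its measured or predicted spirometry columns
#'
#' @param cohort data.frame with `fev1_fvc` and `fev1_pct` columns (fraction
#'   units; percent-scale columns are rescaled by [read_cohort_csv()] at
#'   ingestion).
#' @return `cohort` with `group` and `gold` columns replaced/appended.
#' @export
stage_cohort <- function(cohort) {
  cl <- classify_group(cohort$fev1_fvc, cohort$fev1_pct)
  cohort$group <- cl$group
  cohort$gold <- cl$gold
  cohort
}
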