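# Evaluation suite: regression error metrics, confusion matrices with the
# five derived classification metrics (kept with integer numerators and
# denominators so percentages can be re-derived losslessly), GOLD-stage
# accuracy, and the end-to-end prediction-based staging evaluation.

#' Regression error metrics
#'
#' Computes the coefficient of determination \eqn{R^2 = 1 - SS_{res} /
#' SS_{tot}} (negative when the model underperforms the mean predictor),
#' MAE, MSE, RMSE and the Spearman rank correlation (average ranks on ties)
#' between predictions and ground truth.
#'
#' @param y_true,y_pred equal-length finite numeric vectors, n >= 3.
#' @return list of class `regression_metrics`: `r2`, `mae`, `mse`, `rmse`,
#'   `spearman_rho`, `spearman_p`, `n`. `r2` is `NA` (with a warning) when
#'   `y_true` has zero variance.
#' @export
regression_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("y_true and y_pred lengths differ")
  if (length(y_true) < 3) stop("need at least 3 observations")
  if (!all(is.finite(y_true)) || !all(is.finite(y_pred)))
    stop("non-finite values in y_true or y_pred")
  res <- y_true - y_pred
  mse <- mean(res^2)
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) {
    warning("y_true has zero variance; R^2 is undefined")
    r2 <- NA_real_
  } else r2 <- 1 - sum(res^2) / ss_tot
  if (ss_tot == 0 || stats::sd(y_pred) == 0) {
    rho <- NA_real_; p <- NA_real_
  } else {
    ct <- suppressWarnings(stats::cor.test(y_true, y_pred, method = "spearman",
                                           exact = FALSE))
    rho <- unname(ct$estimate); p <- ct$p.value
  }
  structure(list(r2 = r2, mae = mean(abs(res)), mse = mse, rmse = sqrt(mse),
                 spearman_rho = rho, spearman_p = p, n = length(y_true)),
            class = "regression_metrics")
}

#' @export
print.regression_metrics <- function(x, ...) {
  cat(sprintf("R^2 %.3f | MAE %.4f | MSE %.4f | RMSE %.4f | Spearman rho %.3f (n = %d)\n",
              x$r2, x$mae, x$mse, x$rmse, x$spearman_rho, x$n))
  invisible(x)
}

confusion_metric <- function(num, den) {
  list(num = as.integer(num), den = as.integer(den),
       value = if (den > 0) num / den else NA_real_)
}

#' Confusion report from stored counts
#'
#' Builds the five-metric report (sensitivity, specificity, PPV, NPV,
#' accuracy) directly from integer confusion counts; numerators and
#' denominators are retained so rounded percentages stay reproducible. A
#' zero denominator yields `NA` ("not applicable"), never 0.
#'
#' @param tp,fn,tn,fp integer counts.
#' @param positive name of the positive class (annotation only).
#' @return object of class `confusion_report`.
#' @export
confusion_report_from_counts <- function(tp, fn, tn, fp, positive = "positive") {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
  structure(list(
    tp = as.integer(tp), fn = as.integer(fn), tn = as.integer(tn), fp = as.integer(fp),
    positive = positive,
    sensitivity = confusion_metric(tp, tp + fn),
    specificity = confusion_metric(tn, tn + fp),
    ppv = confusion_metric(tp, tp + fp),
    npv = confusion_metric(tn, tn + fn),
    accuracy = confusion_metric(tp + tn, tp + tn + fp + fn)),
    class = "confusion_report")
}

#' Confusion report from label vectors
#'
#' @param truth,pred equal-length vectors over a declared label set.
#' @param positive the positive class (must be a known label).
#' @param labels the full label set; defaults to the union of levels. A
#'   predicted or true label outside this set is an error.
#' @return object of class `confusion_report`.
#' @export
confusion_report <- function(truth, pred, positive, labels = NULL) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (length(truth) != length(pred)) stop("truth and pred lengths differ")
  if (is.null(labels)) labels <- sort(unique(c(truth, pred)))
  unseen <- setdiff(unique(c(truth, pred)), labels)
  if (length(unseen)) stop("labels outside the declared set: ", paste(unseen, collapse = ", "))
  if (!positive %in% labels) stop("positive class ", positive, " not in the label set")
  tpos <- truth == positive; ppos <- pred == positive
  confusion_report_from_counts(tp = sum(tpos & ppos), fn = sum(tpos & !ppos),
                               tn = sum(!tpos & !ppos), fp = sum(!tpos & ppos),
                               positive = positive)
}

#' Percentages of a confusion report, rounded to integers
#'
#' Companion to the full-precision report: metric values as percentages
#' rounded to the nearest integer, recomputed from the stored counts.
#'
#' @param report a `confusion_report`.
#' @return named numeric vector (NA where a denominator is zero).
#' @export
confusion_percentages <- function(report) {
  v <- vapply(report[c("sensitivity", "specificity", "ppv", "npv", "accuracy")],
              function(m) if (is.na(m$value)) NA_real_ else round(100 * m$value),
              numeric(1))
  names(v) <- c("sensitivity", "specificity", "ppv", "npv", "accuracy")
  v
}

#' @export
print.confusion_report <- function(x, ...) {
  cat(sprintf("Confusion report (positive = %s): TP %d, FN %d, TN %d, FP %d\n",
              x$positive, x$tp, x$fn, x$tn, x$fp))
  for (m in c("sensitivity", "specificity", "ppv", "npv", "accuracy")) {
    mm <- x[[m]]
    if (is.na(mm$value)) cat(sprintf("  %-11s n/a (0 denominator)\n", m))
    else cat(sprintf("  %-11s %d/%d (%.0f%%)\n", m, mm$num, mm$den, 100 * mm$value))
  }
  invisible(x)
}

#' Multi-class staging accuracy
#'
#' Overall accuracy with its numerator/denominator and the stage-by-stage
#' confusion table (used for GOLD I-IV stratification of predicted COPD).
#'
#' @param truth,pred equal-length stage vectors.
#' @param stages declared stage set.
#' @return list of class `multiclass_accuracy`: `accuracy` (num/den/value)
#'   and `table`.
#' @export
multiclass_accuracy <- function(truth, pred, stages = c("I", "II", "III", "IV")) {
  truth <- factor(as.character(truth), levels = stages)
  pred <- factor(as.character(pred), levels = stages)
  if (anyNA(truth) || anyNA(pred)) stop("stages outside the declared set")
  n <- length(truth)
  structure(list(accuracy = confusion_metric(sum(truth == pred), n),
                 table = table(truth = truth, pred = pred)),
            class = "multiclass_accuracy")
}

#' @export
print.multiclass_accuracy <- function(x, ...) {
  a <- x$accuracy
  cat(sprintf("Stage accuracy %d/%d (%.0f%%)\n", a$num, a$den,
              if (a$den > 0) 100 * a$value else NA))
  print(x$table)
  invisible(x)
}

# ---- end-to-end evaluation --------------------------------------------------

#' Train, predict, and evaluate the full staging pipeline on one cohort
#'
#' Splits the cohort, fits the requested model families for both spirometry
#' targets, computes validation regression metrics for every (family,
#' target), selects the best family by mean validation \eqn{R^2}, and runs
#' the prediction-based staging cascade with it:
#' \enumerate{
#'   \item COPD vs non-COPD from the predicted FEV1/FVC (< 0.7), evaluated
#'     against staging of the measured spirometry (positive class COPD);
#'   \item normal vs high-risk from the predicted FEV1% among subjects
#'     predicted non-COPD whose measured-spirometry label is normal or
#'     high-risk (positive class high-risk);
#'   \item GOLD I-IV stage agreement among measured-spirometry COPD
#'     subjects, predicted stage from the predicted FEV1%.
#' }
#' Subjects discordant on the normal/high-risk task are listed with their
#' whole-lung fSAD%/Emph% (the published table of inconsistent cases is the
#' analogue); their count equals FP + FN of that task by construction.
#'
#' @param cohort cohort data.frame (from [generate_cohort()] or
#'   [read_cohort_csv()]).
#' @param seed seed driving the split and the model fits.
#' @param families model families to fit and compare.
#' @param sizes optional explicit `c(n_train, n_validation)` split sizes.
#' @param hyper optional per-family hyperparameter overrides.
#' @return object of class `prm_evaluation_report`.
#' @export
run_full_evaluation <- function(cohort, seed = 1L,
                                families = c("random_forest", "mlp"),
                                sizes = NULL, hyper = list()) {
  split <- split_train_validation(cohort, seed = seed, sizes = sizes)
  models <- train_model_set(split$train, seed = seed, families = families,
                            hyper = hyper)
  val <- split$validation

  regression <- list()
  predictions <- list()
  for (fam in families) {
    predictions[[fam]] <- list()
    for (tg in c("fev1_fvc", "fev1_pct")) {
      p <- predict(models[[fam]][[tg]], val)
      predictions[[fam]][[tg]] <- p
      regression[[fam]][[tg]] <- regression_metrics(val[[tg]], p)
    }
  }
  mean_r2 <- vapply(families, function(f)
    mean(c(regression[[f]]$fev1_fvc$r2, regression[[f]]$fev1_pct$r2)), numeric(1))
  best_family <- families[which.max(mean_r2)]

  pred_ff <- predictions[[best_family]]$fev1_fvc
  pred_fp <- predictions[[best_family]]$fev1_pct
  truth_cl <- classify_group(val$fev1_fvc, val$fev1_pct)
  pred_cl <- classify_group(pred_ff, pred_fp)

  copd_report <- confusion_report(
    ifelse(truth_cl$group == "copd", "copd", "non_copd"),
    ifelse(pred_cl$group == "copd", "copd", "non_copd"),
    positive = "copd", labels = c("copd", "non_copd"))

  nh_idx <- which(pred_cl$group != "copd" & truth_cl$group %in% c("normal", "high_risk"))
  nh_report <- confusion_report(as.character(truth_cl$group[nh_idx]),
                                as.character(pred_cl$group[nh_idx]),
                                positive = "high_risk",
                                labels = c("normal", "high_risk"))

  copd_idx <- which(truth_cl$group == "copd")
  gold <- if (length(copd_idx))
    multiclass_accuracy(as.character(truth_cl$gold[copd_idx]),
                        gold_stage(pred_fp[copd_idx]))
  else NULL

  disc <- nh_idx[truth_cl$group[nh_idx] != pred_cl$group[nh_idx]]
  discordant <- data.frame(
    row = split$indices$validation[disc],
    prm_whole_fsad_pct = val$prm_whole_fsad_pct[disc],
    prm_whole_emph_pct = val$prm_whole_emph_pct[disc],
    group_pft = as.character(truth_cl$group[disc]),
    fev1_pct = val$fev1_pct[disc],
    fev1_fvc = val$fev1_fvc[disc],
    fev1_pct_pred = pred_fp[disc],
    group_model = as.character(pred_cl$group[disc]))

  structure(list(seed = seed, families = families, best_family = best_family,
                 n_train = nrow(split$train), n_validation = nrow(val),
                 regression = regression, copd_report = copd_report,
                 normal_highrisk_report = nh_report, gold = gold,
                 discordant = discordant, models = models,
                 split_indices = split$indices),
            class = "prm_evaluation_report")
}

#' @export
print.prm_evaluation_report <- function(x, ...) {
  cat(sprintf("Pipeline evaluation: %d train / %d validation, best family %s\n",
              x$n_train, x$n_validation, x$best_family))
  for (fam in names(x$regression)) for (tg in names(x$regression[[fam]])) {
    cat(sprintf("  %s / %s: ", fam, tg)); print(x$regression[[fam]][[tg]])
  }
  cat("COPD vs non-COPD:\n"); print(x$copd_report)
  cat("normal vs high-risk (predicted non-COPD):\n"); print(x$normal_highrisk_report)
  if (!is.null(x$gold)) { cat("GOLD stage agreement (measured COPD):\n"); print(x$gold) }
  cat(sprintf("discordant normal/high-risk subjects: %d\n", nrow(x$discordant)))
  invisible(x)
}

# ---- serialization ----------------------------------------------------------

report_metrics_list <- function(x) {
  reg <- lapply(x$regression, function(ff) lapply(ff, function(m)
    m[c("r2", "mae", "mse", "rmse", "spearman_rho", "spearman_p", "n")]))
  conf <- function(r) list(tp = r$tp, fn = r$fn, tn = r$tn, fp = r$fp,
                           positive = r$positive,
                           percentages = as.list(confusion_percentages(r)))
  list(seed = x$seed, best_family = x$best_family,
       n_train = x$n_train, n_validation = x$n_validation,
       regression = reg,
       copd = conf(x$copd_report),
       normal_highrisk = conf(x$normal_highrisk_report),
       gold_accuracy = if (is.null(x$gold)) NULL else x$gold$accuracy,
       discordant = x$discordant)
}

#' Serialize an evaluation report to JSON
#' @param report a `prm_evaluation_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(report, path) {
  jsonlite::write_json(report_metrics_list(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(path)
}

#' Read back a serialized evaluation report
#' @param path JSON path from [write_evaluation_report()].
#' @return nested list of metrics (not the fitted models).
#' @export
read_evaluation_report <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
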