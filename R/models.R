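# Regression of spirometry from the 76-column feature table. Two families:
# a random forest (the primary model) and a single-hidden-layer perceptron
# baseline on standardized inputs. One fitted model per (family, target).

#' Split a cohort into training and validation sets
#'
#' Seeded random partition. By default the validation set holds
#' `round(n / 5)` subjects (a 4:1 split); explicit sizes override the rule
#' for designs where the published counts are not an exact ratio.
#'
#' @param cohort data.frame of subjects.
#' @param seed integer seed for the shuffle.
#' @param sizes optional integer length-2 `c(n_train, n_validation)`; must
#'   sum to `nrow(cohort)`.
#' @return list with `train` and `validation` data.frames and the integer
#'   index vectors in `indices`.
#' @export
split_train_validation <- function(cohort, seed = 1L, sizes = NULL) {
  n <- nrow(cohort)
  if (n < 5) stop("need at least 5 subjects to split 4:1")
  if (is.null(sizes)) {
    n_val <- round(n / 5)
  } else {
    if (length(sizes) != 2L || sum(sizes) != n)
      stop(sprintf("explicit sizes must sum to n = %d", n))
    n_val <- sizes[2]
  }
  set.seed(seed)
  perm <- sample.int(n)
  val_idx <- sort(perm[seq_len(n_val)])
  train_idx <- sort(perm[-seq_len(n_val)])
  list(train = cohort[train_idx, , drop = FALSE],
       validation = cohort[val_idx, , drop = FALSE],
       indices = list(train = train_idx, validation = val_idx))
}

#' Specification of a spirometry regressor
#'
#' @param family `"random_forest"` or `"mlp"`.
#' @param target `"fev1_fvc"` or `"fev1_pct"`.
#' @param seed integer seed for the fit.
#' @param hyper named list of hyperparameter overrides. Random forest:
#'   `ntree` (500), `mtry` (`ceiling(p / 3)`), `nodesize` (5), `replace`
#'   (TRUE), `sampsize`. MLP: `size` (32), `decay` (1e-3), `maxit` (500).
#' @return a `regressor_spec` list.
#' @export
regressor_spec <- function(family = c("random_forest", "mlp"),
                           target = c("fev1_fvc", "fev1_pct"),
                           seed = 1L, hyper = list()) {
  structure(list(family = match.arg(family), target = match.arg(target),
                 seed = as.integer(seed), hyper = hyper),
            class = "regressor_spec")
}

feature_matrix <- function(data, features = prm_feature_columns()) {
  missing <- setdiff(features, names(data))
  if (length(missing))
    stop("feature columns missing from data: ", paste(missing, collapse = ", "))
  x <- as.matrix(data[, features, drop = FALSE])
  if (!is.numeric(x)) stop("feature columns must be numeric")
  x
}

#' Train a spirometry regressor
#'
#' Fits the specified family on the 76 feature columns of `train`. Rows
#' with missing feature or target values are dropped with a message. The
#' random forest records permutation feature importance; the MLP records
#' its final training loss and standardization parameters.
#'
#' @param spec a [regressor_spec()].
#' @param train training data.frame containing the feature columns and the
#'   target column.
#' @param features feature column names (default the canonical 76).
#' @return object of class `prm_regressor`.
#' @export
train_regressor <- function(spec, train, features = prm_feature_columns()) {
  stopifnot(inherits(spec, "regressor_spec"))
  x <- feature_matrix(train, features)
  y <- train[[spec$target]]
  if (is.null(y)) stop("target column ", spec$target, " not found in training data")
  if (!all(is.finite(y))) stop("non-finite target values in training data")
  keep <- stats::complete.cases(x)
  if (!all(keep)) {
    message(sprintf("dropping %d rows with missing features", sum(!keep)))
    x <- x[keep, , drop = FALSE]; y <- y[keep]
  }
  if (nrow(x) < 10) stop("need at least 10 complete training rows")
  h <- spec$hyper
  set.seed(spec$seed)
  if (spec$family == "random_forest") {
    args <- list(x = x, y = y,
                 ntree = h$ntree %||% 500L,
                 mtry = h$mtry %||% ceiling(ncol(x) / 3),
                 nodesize = h$nodesize %||% 5L,
                 replace = h$replace %||% TRUE,
                 importance = TRUE)
    if (!is.null(h$sampsize)) args$sampsize <- h$sampsize
    fit <- do.call(randomForest::randomForest, args)
    extras <- list(importance = randomForest::importance(fit))
  } else {
    center <- colMeans(x); scl <- apply(x, 2, stats::sd)
    scl[scl == 0] <- 1
    xs <- scale(x, center, scl)
    fit <- nnet::nnet(xs, y, size = h$size %||% 32L, linout = TRUE,
                      decay = h$decay %||% 1e-3, maxit = h$maxit %||% 500L,
                      MaxNWts = 50000L, trace = FALSE)
    extras <- list(center = center, scale = scl, final_loss = fit$value)
  }
  structure(c(list(fit = fit, spec = spec, features = features), extras),
            class = "prm_regressor")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict spirometry from a fitted regressor
#'
#' Predictions are clipped to the physiologic domain (0, 1.6]. A feature
#' layout that does not match training is an error naming the offending
#' columns.
#'
#' @param object a `prm_regressor`.
#' @param newdata data.frame or matrix with the training feature columns.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.prm_regressor <- function(object, newdata, ...) {
  x <- feature_matrix(as.data.frame(newdata), object$features)
  p <- if (object$spec$family == "random_forest") {
    as.numeric(stats::predict(object$fit, x))
  } else {
    as.numeric(stats::predict(object$fit, scale(x, object$center, object$scale)))
  }
  pmin(pmax(p, 1e-3), 1.6)
}

#' @export
print.prm_regressor <- function(x, ...) {
  cat(sprintf("%s regressor for %s (seed %d, %d features)\n",
              x$spec$family, x$spec$target, x$spec$seed, length(x$features)))
  invisible(x)
}

#' Train the full model set (both families, both targets)
#'
#' @param train training data.frame.
#' @param seed base seed; each (family, target) fit gets a distinct derived
#'   seed.
#' @param families model families to fit.
#' @param hyper optional named list `hyper[[family]]` of overrides.
#' @return nested list `models[[family]][[target]]` of `prm_regressor`s.
#' @export
train_model_set <- function(train, seed = 1L,
                            families = c("random_forest", "mlp"),
                            hyper = list()) {
  targets <- c("fev1_fvc", "fev1_pct")
  models <- list()
  k <- 0L
  for (fam in families) {
    models[[fam]] <- list()
    for (tg in targets) {
      k <- k + 1L
      spec <- regressor_spec(fam, tg, seed = seed + k,
                             hyper = hyper[[fam]] %||% list())
      models[[fam]][[tg]] <- train_regressor(spec, train)
    }
  }
  models
}
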