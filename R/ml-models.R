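#' Gradient-boosting hyperparameters
#'
#' Fixed hyperparameter set for the boosted-tree classifier: shallow trees
#' (depth 3) to keep interactions low-order and avoid overfitting, learning
#' rate 0.1, 100 boosting rounds, and 80% row and feature subsampling per
#' tree. The objective is always binary classification with a logistic link.
#'
#' @param max_depth Maximum tree depth (default 3).
#' @param learning_rate Shrinkage per round (default 0.1).
#' @param n_rounds Number of boosting rounds/trees (default 100).
#' @param row_subsample Fraction of training rows sampled per tree
#'   (default 0.8).
#' @param feature_subsample Fraction of features sampled per tree
#'   (default 0.8).
#'
#' @return An object of class `boost_params`.
#' @export
boost_params <- function(max_depth = 3L, learning_rate = 0.1, n_rounds = 100L,
                         row_subsample = 0.8, feature_subsample = 0.8) {
  if (max_depth < 1) stop("max_depth must be >= 1")
  if (n_rounds < 1) stop("n_rounds must be >= 1")
  if (row_subsample <= 0 || row_subsample > 1 ||
      feature_subsample <= 0 || feature_subsample > 1) {
    stop("subsample fractions must be in (0, 1]")
  }
  structure(list(max_depth = as.integer(max_depth),
                 learning_rate = learning_rate,
                 n_rounds = as.integer(n_rounds),
                 row_subsample = row_subsample,
                 feature_subsample = feature_subsample),
            class = "boost_params")
}

#' Logistic-regression comparator parameters
#'
#' L2-regularised (ridge) logistic regression, optionally augmented with all
#' pairwise interaction products of the scaled features so that multiplicative
#' effects are at least representable by the linear model. The ridge penalty
#' corresponds to a unit-weight L2 penalty on the coefficients (glmnet
#' `alpha = 0`, `lambda = 1/n_train`). `max_iterations` is a quasi-Newton
#' iteration budget; it is translated to the coordinate-descent pass budget of
#' the underlying solver, whose iterations are much finer-grained.
#'
#' @param tolerance Convergence tolerance of the solver (default 1e-4).
#' @param max_iterations Optimiser iteration budget (default 100).
#' @param include_pairwise_interactions Add all distinct pairwise products of
#'   the scaled features (default `TRUE`).
#'
#' @return An object of class `logistic_params`.
#' @export
logistic_params <- function(tolerance = 1e-4, max_iterations = 100L,
                            include_pairwise_interactions = TRUE) {
  if (tolerance <= 0) stop("tolerance must be positive")
  if (max_iterations < 1) stop("max_iterations must be >= 1")
  structure(list(tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 include_pairwise_interactions = isTRUE(include_pairwise_interactions)),
            class = "logistic_params")
}

#' Binarise outcome changes into response labels
#'
#' Label 1 when the outcome change is at or above the clinically meaningful
#' threshold, 0 below it.
#'
#' @param outcome_changes Numeric vector of outcome changes; must be finite.
#' @param threshold Clinically meaningful change (default 5).
#'
#' @return Integer 0/1 labels.
#' @export
#' @examples
#' binarize_outcome(c(5, 4.999, -2, 11))
binarize_outcome <- function(outcome_changes, threshold = 5) {
  if (any(!is.finite(outcome_changes))) {
    stop("outcome changes must be finite")
  }
  as.integer(outcome_changes >= threshold)
}

#' Centre and scale non-binary features
#'
#' Continuous columns are centred and scaled to unit variance using statistics
#' computed on `fit_rows` only (so cross-validation folds can be scaled
#' without leakage from held-out rows); binary columns pass through unchanged.
#' A continuous column that is constant on the fit rows is left unscaled with
#' a warning.
#'
#' @param features Numeric matrix or data frame of features.
#' @param binary_mask Optional logical vector marking binary columns; by
#'   default a column whose observed values all lie in \{0, 1\} is treated as
#'   binary.
#' @param fit_rows Rows used to estimate means and standard deviations
#'   (default: all rows).
#'
#' @return A numeric matrix of the same shape, scaled on all rows with the
#'   fit-row statistics.
#' @export
standardize <- function(features, binary_mask = NULL, fit_rows = NULL) {
  m <- as.matrix(features)
  storage.mode(m) <- "double"
  if (is.null(fit_rows)) fit_rows <- seq_len(nrow(m))
  if (length(fit_rows) == 0L) stop("fit_rows must be non-empty")
  if (is.null(binary_mask)) {
    binary_mask <- apply(m, 2L, function(col) all(col %in% c(0, 1)))
  }
  stopifnot(length(binary_mask) == ncol(m))
  for (j in which(!binary_mask)) {
    mu <- mean(m[fit_rows, j])
    s <- stats::sd(m[fit_rows, j])
    if (!is.finite(s) || s == 0) {
      warning("column ", colnames(m)[j] %||% j,
              " is constant on the fit rows; left unscaled")
      next
    }
    m[, j] <- (m[, j] - mu) / s
  }
  m
}

# All distinct pairwise products of the columns of m, named "a:b".
pairwise_interactions <- function(m) {
  p <- ncol(m)
  if (p < 2L) return(m)
  nm <- colnames(m) %||% paste0("f", seq_len(p))
  pairs <- utils::combn(p, 2L)
  inter <- matrix(0, nrow = nrow(m), ncol = ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    inter[, k] <- m[, pairs[1L, k]] * m[, pairs[2L, k]]
  }
  colnames(inter) <- paste(nm[pairs[1L, ]], nm[pairs[2L, ]], sep = ":")
  colnames(m) <- nm
  cbind(m, inter)
}

#' Out-of-fold cross-validated predictions
#'
#' Splits patients into `k_folds` shuffled folds of near-equal size; for each
#' fold, fits the classifier on the remaining folds (feature scaling fitted on
#' the training rows only; the logistic variant additionally appends all
#' pairwise interaction products) and predicts the held-out fold. Every
#' patient is therefore predicted exactly once, by a model that never saw
#' them. Deterministic under a fixed seed.
#'
#' @param features Numeric matrix or data frame of covariates (no outcome or
#'   truth columns).
#' @param labels Binary 0/1 response labels, one per row.
#' @param model_params A [boost_params()] or [logistic_params()] object.
#' @param k_folds Number of folds (default 5); must not exceed the number of
#'   rows.
#' @param seed Optional seed controlling the fold shuffle and the stochastic
#'   row/feature subsampling of the boosted learner.
#' @param patient_ids Optional patient identifiers (default: row index).
#'
#' @return An object of class `oof_fit`: a list with `predictions` (data frame
#'   `patient_id`, `fold`, `prob`, `predicted_label`, in input row order),
#'   `learner` (`"boost"` or `"logistic"`), per-fold fitted models, and the
#'   held-out feature matrices needed for Shapley attribution.
#' @export
oof_predict <- function(features, labels, model_params, k_folds = 5L,
                        seed = NULL, patient_ids = NULL) {
  m <- as.matrix(features)
  storage.mode(m) <- "double"
  if (is.null(colnames(m))) colnames(m) <- paste0("f", seq_len(ncol(m)))
  n <- nrow(m)
  labels <- as.integer(labels)
  stopifnot(length(labels) == n, all(labels %in% c(0L, 1L)))
  if (k_folds < 2L || k_folds > n) stop("k_folds must be in [2, n]")
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present overall")
  }
  if (is.null(patient_ids)) patient_ids <- seq_len(n)
  stopifnot(length(patient_ids) == n, !anyDuplicated(patient_ids))

  learner <- if (inherits(model_params, "boost_params")) {
    "boost"
  } else if (inherits(model_params, "logistic_params")) {
    "logistic"
  } else {
    stop("model_params must be boost_params() or logistic_params()")
  }

  if (!is.null(seed)) set.seed(seed)
  fold <- sample(rep_len(seq_len(k_folds), n))
  binary_mask <- apply(m, 2L, function(col) all(col %in% c(0, 1)))

  prob <- numeric(n)
  models <- vector("list", k_folds)
  heldout <- vector("list", k_folds)
  for (f in seq_len(k_folds)) {
    test_rows <- which(fold == f)
    train_rows <- which(fold != f)
    if (length(unique(labels[train_rows])) < 2L) {
      stop(sprintf("training split for fold %d contains a single class", f))
    }
    ms <- standardize(m, binary_mask = binary_mask, fit_rows = train_rows)
    if (learner == "boost") {
      dtrain <- xgboost::xgb.DMatrix(ms[train_rows, , drop = FALSE],
                                     label = labels[train_rows])
      bst <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      eval_metric = "logloss",
                      max_depth = model_params$max_depth,
                      eta = model_params$learning_rate,
                      subsample = model_params$row_subsample,
                      colsample_bytree = model_params$feature_subsample,
                      nthread = 1L),
        data = dtrain, nrounds = model_params$n_rounds, verbose = 0)
      new_m <- ms[test_rows, , drop = FALSE]
      prob[test_rows] <- predict(bst, new_m)
      models[[f]] <- bst
      heldout[[f]] <- list(rows = test_rows, scaled = new_m)
    } else {
      if (model_params$include_pairwise_interactions) {
        ms_full <- pairwise_interactions(ms)
      } else {
        ms_full <- ms
      }
      fit <- glmnet::glmnet(ms_full[train_rows, , drop = FALSE],
                            factor(labels[train_rows], levels = c(0L, 1L)),
                            family = "binomial", alpha = 0,
                            lambda = 1 / length(train_rows),
                            standardize = FALSE,
                            thresh = model_params$tolerance,
                            maxit = model_params$max_iterations * 1000L)
      prob[test_rows] <- as.numeric(
        predict(fit, ms_full[test_rows, , drop = FALSE], type = "response"))
      models[[f]] <- fit
      heldout[[f]] <- list(rows = test_rows,
                           scaled = ms_full[test_rows, , drop = FALSE])
    }
  }

  structure(list(
    predictions = data.frame(patient_id = patient_ids,
                             fold = fold,
                             prob = prob,
                             predicted_label = as.integer(prob >= 0.5)),
    learner = learner,
    model_params = model_params,
    models = models,
    heldout = heldout,
    features = m,
    labels = labels,
    k_folds = k_folds
  ), class = "oof_fit")
}

#' Confusion-matrix evaluation of out-of-fold predictions
#'
#' Tabulates predictions against a reference labelling (either the noisy
#' trial-outcome labels or the simulator's ground truth) and reports the
#' standard classification metrics with a normal-approximation binomial
#' confidence interval for accuracy.
#'
#' @param predictions An `oof_fit` object from [oof_predict()], or a data
#'   frame with columns `patient_id` and `predicted_label`.
#' @param reference_labels Binary reference labels. Either unnamed and in the
#'   same row order as the predictions, or named by patient id.
#'
#' @return An object of class `confusion_summary`: counts `tp`, `fp`, `fn`,
#'   `tn`, rates `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`, and
#'   `accuracy_ci`.
#' @export
evaluate <- function(predictions, reference_labels) {
  preds <- if (inherits(predictions, "oof_fit")) {
    predictions$predictions
  } else {
    predictions
  }
  stopifnot(all(c("patient_id", "predicted_label") %in% names(preds)))
  if (!is.null(names(reference_labels))) {
    idx <- match(as.character(preds$patient_id), names(reference_labels))
    if (anyNA(idx)) stop("reference labels missing for some patient ids")
    ref <- as.integer(reference_labels[idx])
  } else {
    if (length(reference_labels) != nrow(preds)) {
      stop("reference labels must match the predicted patients")
    }
    ref <- as.integer(reference_labels)
  }
  stopifnot(all(ref %in% c(0L, 1L)))
  pred <- preds$predicted_label
  tp <- sum(pred == 1L & ref == 1L)
  fp <- sum(pred == 1L & ref == 0L)
  fn <- sum(pred == 0L & ref == 1L)
  tn <- sum(pred == 0L & ref == 0L)
  n <- tp + fp + fn + tn
  acc <- (tp + tn) / n
  structure(list(
    tp = tp, fp = fp, fn = fn, tn = tn, n = n,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    accuracy = acc,
    accuracy_ci = accuracy_ci(tp + tn, n)
  ), class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("confusion summary (n = %d)\n", x$n))
  cat(sprintf("          ref 1  ref 0\n"))
  cat(sprintf("  pred 1  %5d  %5d\n", x$tp, x$fp))
  cat(sprintf("  pred 0  %5d  %5d\n", x$fn, x$tn))
  cat(sprintf("  accuracy %.3f (95%% CI %.3f-%.3f)\n",
              x$accuracy, x$accuracy_ci[1], x$accuracy_ci[2]))
  cat(sprintf("  sens %.3f  spec %.3f  ppv %.3f  npv %.3f\n",
              x$sensitivity, x$specificity, x$ppv, x$npv))
  invisible(x)
}

#' Normal-approximation binomial confidence interval for accuracy
#'
#' `p_hat +/- 1.96 * sqrt(p_hat (1 - p_hat) / total)`, clipped to `[0, 1]`.
#'
#' @param correct Number of correct predictions.
#' @param total Number of predictions (>= 1).
#'
#' @return Length-2 numeric vector `c(low, high)`.
#' @export
#' @examples
#' accuracy_ci(498, 509)
accuracy_ci <- function(correct, total) {
  if (total < 1) stop("total must be >= 1")
  if (correct < 0 || correct > total) stop("correct must be in [0, total]")
  p <- correct / total
  half <- 1.96 * sqrt(p * (1 - p) / total)
  c(max(0, p - half), min(1, p + half))
}
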