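#' Shapley attributions for out-of-fold boosted predictions
#'
#' Computes exact tree-path Shapley (SHAP) attributions on the log-odds
#' margin scale. By default each fold's model explains its own held-out
#' patients, so the explained population is exactly the out-of-fold predicted
#' population; with `refit = TRUE` one model is refitted on all rows and
#' explains every patient. Per patient, the base value plus the feature
#' attributions reproduces the model's margin output (additivity).
#'
#' @param fit An `oof_fit` from [oof_predict()] with the boosted learner.
#' @param refit Explain with a single model refitted on all rows instead of
#'   the fold models (default `FALSE`).
#' @param seed Seed for the refit (ignored when `refit = FALSE`).
#'
#' @return An object of class `attribution_table`: list with `attribution`
#'   (patients x features matrix, log-odds units), `base_value` (per patient),
#'   `patient_ids`, `predicted_label`, `feature_values` (raw, unscaled) and
#'   `feature_names`.
#' @export
attribute <- function(fit, refit = FALSE, seed = NULL) {
  stopifnot(inherits(fit, "oof_fit"))
  if (fit$learner != "boost") {
    stop("Shapley attribution is implemented for the boosted learner only")
  }
  n <- nrow(fit$features)
  p <- ncol(fit$features)
  contrib <- matrix(NA_real_, n, p,
                    dimnames = list(NULL, colnames(fit$features)))
  base <- numeric(n)
  if (refit) {
    if (!is.null(seed)) set.seed(seed)
    ms <- standardize(fit$features)
    bp <- fit$model_params
    dtrain <- xgboost::xgb.DMatrix(ms, label = fit$labels)
    bst <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", eval_metric = "logloss",
                    max_depth = bp$max_depth, eta = bp$learning_rate,
                    subsample = bp$row_subsample,
                    colsample_bytree = bp$feature_subsample, nthread = 1L),
      data = dtrain, nrounds = bp$n_rounds, verbose = 0)
    sh <- predict(bst, ms, predcontrib = TRUE)
    contrib[, ] <- sh[, seq_len(p), drop = FALSE]
    base <- sh[, p + 1L]
  } else {
    for (f in seq_len(fit$k_folds)) {
      ho <- fit$heldout[[f]]
      sh <- predict(fit$models[[f]], ho$scaled, predcontrib = TRUE)
      contrib[ho$rows, ] <- sh[, seq_len(p), drop = FALSE]
      base[ho$rows] <- sh[, p + 1L]
    }
  }
  structure(list(
    attribution = contrib,
    base_value = base,
    patient_ids = fit$predictions$patient_id,
    predicted_label = fit$predictions$predicted_label,
    feature_values = fit$features,
    feature_names = colnames(fit$features)
  ), class = "attribution_table")
}

#' Rank features by summed attribution magnitude
#'
#' Features sorted by the sum over patients of the absolute Shapley
#' attribution, descending; ties broken alphabetically by feature name.
#'
#' @param table An `attribution_table` from [attribute()].
#'
#' @return Data frame with columns `feature` and `importance`, most
#'   influential first.
#' @export
rank_features <- function(table) {
  stopifnot(inherits(table, "attribution_table"))
  if (nrow(table$attribution) == 0L) stop("attribution table is empty")
  imp <- colSums(abs(table$attribution))
  ord <- order(-imp, names(imp))
  data.frame(feature = names(imp)[ord], importance = unname(imp[ord]),
             row.names = NULL)
}

#' Conditional attribution slice
#'
#' Restricts patients with interval or equality filters on the raw feature
#' values, then returns (value, attribution, prediction) points for the
#' target feature together with per-value-bin proportions of
#' responsive predictions -- the scatter-plus-histogram view used to read
#' decision thresholds off the fitted model.
#'
#' @param table An `attribution_table` from [attribute()].
#' @param target_feature Feature whose values and attributions are plotted.
#' @param filters Named list of conditions on raw feature values: a length-2
#'   numeric vector is an inclusive interval, a single value is an equality
#'   filter (for binary features).
#' @param bin_width Width of the value bins for the prediction-proportion
#'   overlay (default 1, i.e. unit integer bins; binary features always get
#'   one bin per level).
#'
#' @return An object of class `shap_slice`: list with `points` (data frame
#'   `patient_id`, `value`, `attribution`, `predicted_label`) and
#'   `proportions` (data frame `bin`, `n`, `prop_responsive`). Empty filters
#'   results give zero-row data frames, not an error.
#' @export
slice <- function(table, target_feature, filters = list(), bin_width = 1) {
  stopifnot(inherits(table, "attribution_table"))
  feats <- table$feature_values
  if (!target_feature %in% colnames(feats)) {
    stop("unknown feature: ", target_feature)
  }
  keep <- rep(TRUE, nrow(feats))
  for (nm in names(filters)) {
    if (!nm %in% colnames(feats)) stop("filter references unknown feature: ", nm)
    cond <- filters[[nm]]
    keep <- keep & if (length(cond) == 2L) {
      feats[, nm] >= cond[1] & feats[, nm] <= cond[2]
    } else {
      feats[, nm] == cond
    }
  }
  v <- feats[keep, target_feature]
  pts <- data.frame(patient_id = table$patient_ids[keep],
                    value = v,
                    attribution = table$attribution[keep, target_feature],
                    predicted_label = table$predicted_label[keep])
  props <- if (nrow(pts) == 0L) {
    data.frame(bin = numeric(0), n = integer(0), prop_responsive = numeric(0))
  } else {
    bin <- if (all(v %in% c(0, 1))) v else floor(v / bin_width) * bin_width
    agg <- stats::aggregate(pts$predicted_label, by = list(bin = bin),
                            FUN = function(l) c(n = length(l), prop = mean(l)))
    data.frame(bin = agg$bin,
               n = as.integer(agg$x[, "n"]),
               prop_responsive = agg$x[, "prop"])
  }
  structure(list(points = pts, proportions = props,
                 target_feature = target_feature, filters = filters),
            class = "shap_slice")
}
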