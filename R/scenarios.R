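#' Scenario configuration
#'
#' Bundles everything a scenario run needs: cohort size, master seed, the
#' response rule and outcome model, learner hyperparameters, the noisy
#' variable grid for the excess sweep, and the replicate count and success
#' criterion for the power analysis.
#'
#' @param n_patients Cohort size (default 1000).
#' @param master_seed Master seed; every random component of a run is derived
#'   from it.
#' @param scenario One of `"baseline"`, `"deficiency"`, `"excess"`, `"power"`.
#' @param noise_grid Ascending counts of noisy variables for the excess sweep
#'   (default 5, 105, 205, ... up to 10000, a +100 schedule).
#' @param n_replicates Number of end-to-end replicates for the power analysis
#'   (default 500).
#' @param success_accuracy Ground-truth accuracy a replicate must exceed to
#'   count as a successful detection (default 0.90).
#' @param rule A [response_rule()].
#' @param model An [outcome_model()].
#' @param boost A [boost_params()].
#' @param logistic A [logistic_params()].
#' @param drop_variable Variable withheld from ML training in the deficiency
#'   scenario (default `"z"`).
#'
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(n_patients = 1000L, master_seed = 1L,
                            scenario = c("baseline", "deficiency",
                                         "excess", "power"),
                            noise_grid = seq(5L, 10000L, by = 100L),
                            n_replicates = 500L, success_accuracy = 0.90,
                            rule = response_rule(), model = outcome_model(),
                            boost = boost_params(),
                            logistic = logistic_params(),
                            drop_variable = "z") {
  scenario <- match.arg(scenario)
  if (n_patients < 2) stop("n_patients must be >= 2")
  if (is.unsorted(noise_grid, strictly = TRUE)) {
    stop("noise_grid must be strictly ascending")
  }
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (success_accuracy <= 0 || success_accuracy >= 1) {
    stop("success_accuracy must be in (0, 1)")
  }
  structure(list(n_patients = as.integer(n_patients),
                 master_seed = as.integer(master_seed),
                 scenario = scenario,
                 noise_grid = as.integer(noise_grid),
                 n_replicates = as.integer(n_replicates),
                 success_accuracy = success_accuracy,
                 rule = rule, model = model,
                 boost = boost, logistic = logistic,
                 drop_variable = drop_variable),
            class = "scenario_config")
}

# Covariate columns available to the learners (everything except identifiers,
# allocation, truth and outcome).
ml_feature_names <- function(trial) {
  setdiff(names(trial),
          c("patient_id", "arm", "responsive_truth", "outcome_change"))
}

# Fit one learner out-of-fold on the treatment arm and evaluate against both
# the noisy outcome labels and the ground truth.
run_treatment_ml <- function(trial, params, threshold, seed, drop = NULL) {
  treated <- trial[trial$arm == "treatment", , drop = FALSE]
  feats <- treated[, ml_feature_names(treated), drop = FALSE]
  if (!is.null(drop)) {
    for (d in drop) feats <- remove_variable(feats, d)
  }
  labels <- binarize_outcome(treated$outcome_change, threshold)
  fit <- oof_predict(feats, labels, params, k_folds = 5L, seed = seed,
                     patient_ids = treated$patient_id)
  list(fit = fit,
       vs_outcome = evaluate(fit, labels),
       vs_truth = evaluate(fit, treated$responsive_truth))
}

# Shared body of the baseline and deficiency scenarios.
run_single_trial_scenario <- function(config, drop = NULL) {
  seeds <- derive_seeds(config$master_seed, 6L)
  trial <- simulate_trial(config$n_patients, rule = config$rule,
                          model = config$model, seed = config$master_seed)
  threshold <- config$model$clinically_meaningful_threshold
  treated <- trial$arm == "treatment"

  traditional <- list(
    forest = subgroup_effects(trial),
    nnt = number_needed_to_treat(trial$outcome_change[treated],
                                 trial$outcome_change[!treated],
                                 threshold = threshold),
    comparisons = do.call(rbind, lapply(
      c("age", "sex", "v1", "v2", "x", "y", "z"),
      function(v) compare_by_truth(trial, v))),
    detectable = detectable_effect(n_per_arm = config$n_patients / 2,
                                   sd = config$model$sigma)
  )

  boost <- run_treatment_ml(trial, config$boost, threshold,
                            seed = seeds[["extra1"]], drop = drop)
  logistic <- run_treatment_ml(trial, config$logistic, threshold,
                               seed = seeds[["extra2"]], drop = drop)

  shap <- attribute(boost$fit)
  ranking <- rank_features(shap)
  rl <- config$rule
  slices <- list()
  if ("x" %in% shap$feature_names) {
    slices$x <- slice(shap, "x")
  }
  if (all(c("x", "y") %in% shap$feature_names)) {
    slices$y <- slice(shap, "y",
                      filters = list(x = c(-Inf, rl$x_mid_low - 1L)))
  }
  if (all(c("x", "y", "z") %in% shap$feature_names)) {
    slices$z <- slice(shap, "z",
                      filters = list(x = c(-Inf, rl$x_mid_low - 1L),
                                     y = c(rl$y_low, rl$y_high)))
  }

  structure(list(
    scenario = if (is.null(drop)) "baseline" else "deficiency",
    omitted = drop,
    config = config,
    trial = trial,
    traditional = traditional,
    ml = list(boost = boost, logistic = logistic),
    ranking = ranking,
    slices = slices,
    provenance = list(master_seed = config$master_seed,
                      seeds = as.list(seeds),
                      config_hash = config_hash(config))
  ), class = "scenario_result")
}

#' Run the baseline scenario
#'
#' Simulates one complete trial, performs the traditional analysis (overall
#' and subgroup effect estimates, NNT, responsive-vs-non-responsive
#' comparisons), fits the boosted and logistic learners out-of-fold on the
#' treatment arm, evaluates each against the trial-outcome labels and the
#' ground truth, and computes the Shapley ranking and conditional slices.
#'
#' @param config A [scenario_config()].
#'
#' @return A `scenario_result` list; see [write_report()] for serialisation.
#' @export
run_baseline <- function(config) {
  run_single_trial_scenario(config, drop = NULL)
}

#' Run the data-deficiency scenario
#'
#' Identical trial to the baseline under the same master seed (same cohort,
#' allocation and outcomes), but the configured variable (default Z) is
#' withheld from the learners before training. Traditional analysis is
#' unaffected by the missing covariate's absence from the models.
#'
#' @param config A [scenario_config()].
#'
#' @return A `scenario_result` with `omitted` recording the withheld variable.
#' @export
run_deficiency <- function(config) {
  run_single_trial_scenario(config, drop = config$drop_variable)
}

#' Run the data-excess sweep
#'
#' For each grid point, re-simulates the whole cohort with that many
#' appended noisy variables (fresh seed per point), fits the boosted learner
#' out-of-fold on the treatment arm, and records accuracy against the
#' trial-outcome labels and against ground truth, plus the top-ranked
#' features.
#'
#' @param config A [scenario_config()]; `config$noise_grid` defines the
#'   sweep.
#' @param resample Re-draw the cohort at every grid point (default `TRUE`);
#'   with `FALSE` one fixed trial (master seed) is reused and only the noise
#'   bank is redrawn, for ablation.
#'
#' @return A data frame (class `excess_curve`) with one row per grid point:
#'   `n_noisy`, accuracies and CIs versus outcome labels and truth, and the
#'   top three features by Shapley importance.
#' @export
run_excess <- function(config, resample = TRUE) {
  grid <- config$noise_grid
  point_seeds <- derive_seeds(config$master_seed, length(grid) + 1L)
  threshold <- config$model$clinically_meaningful_threshold
  base_trial <- if (!resample) {
    simulate_trial(config$n_patients, rule = config$rule,
                   model = config$model, seed = config$master_seed)
  }
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    ps <- point_seeds[[i]]
    sub <- derive_seeds(ps, 6L)
    trial <- if (resample) {
      simulate_trial(config$n_patients, rule = config$rule,
                     model = config$model, seed = ps)
    } else {
      base_trial
    }
    if (grid[i] > 0L) {
      trial <- add_noise_variables(trial, noise_spec(grid[i]),
                                   seed = sub[["noise"]])
    }
    res <- run_treatment_ml(trial, config$boost, threshold,
                            seed = sub[["extra1"]])
    top <- utils::head(rank_features(attribute(res$fit))$feature, 3L)
    rows[[i]] <- data.frame(
      n_noisy = grid[i],
      acc_outcome = res$vs_outcome$accuracy,
      acc_outcome_lo = res$vs_outcome$accuracy_ci[1],
      acc_outcome_hi = res$vs_outcome$accuracy_ci[2],
      acc_truth = res$vs_truth$accuracy,
      acc_truth_lo = res$vs_truth$accuracy_ci[1],
      acc_truth_hi = res$vs_truth$accuracy_ci[2],
      top_features = paste(top, collapse = ",")
    )
  }
  curve <- do.call(rbind, rows)
  attr(curve, "provenance") <- list(master_seed = config$master_seed,
                                    point_seeds = as.list(point_seeds[seq_along(grid)]),
                                    config_hash = config_hash(config))
  class(curve) <- c("excess_curve", class(curve))
  curve
}

#' Run the replicate power analysis
#'
#' Repeats the entire pipeline -- cohort generation, randomisation, outcomes,
#' boosted out-of-fold prediction on the treatment arm -- for
#' `config$n_replicates` independent master seeds, and counts the replicates
#' whose ground-truth accuracy exceeds `config$success_accuracy`.
#'
#' @param config A [scenario_config()].
#'
#' @return An object of class `power_result`: `n_runs`, `n_success`,
#'   `success_fraction` and the per-run ground-truth accuracies.
#' @export
run_power <- function(config) {
  rep_seeds <- derive_seeds(config$master_seed, config$n_replicates)
  threshold <- config$model$clinically_meaningful_threshold
  acc <- vapply(seq_len(config$n_replicates), function(i) {
    ps <- rep_seeds[[i]]
    trial <- simulate_trial(config$n_patients, rule = config$rule,
                            model = config$model, seed = ps)
    res <- run_treatment_ml(trial, config$boost, threshold,
                            seed = derive_seeds(ps, 6L)[["extra1"]])
    res$vs_truth$accuracy
  }, numeric(1))
  n_success <- sum(acc > config$success_accuracy)
  structure(list(n_runs = config$n_replicates,
                 n_success = n_success,
                 success_fraction = n_success / config$n_replicates,
                 accuracies = acc,
                 provenance = list(master_seed = config$master_seed,
                                   config_hash = config_hash(config))),
            class = "power_result")
}

confusion_to_list <- function(cs) {
  list(tp = cs$tp, fp = cs$fp, fn = cs$fn, tn = cs$tn, n = cs$n,
       sensitivity = cs$sensitivity, specificity = cs$specificity,
       ppv = cs$ppv, npv = cs$npv, accuracy = cs$accuracy,
       accuracy_ci = as.list(stats::setNames(cs$accuracy_ci, c("low", "high"))))
}

# Recursively drop S3 classes so configuration objects serialise as plain
# JSON maps.
strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else x
}

# Stable checksum of a configuration's JSON rendering, for manifests.
config_hash <- function(config) {
  s <- as.character(jsonlite::toJSON(strip_classes(config), auto_unbox = TRUE,
                                     digits = NA, force = TRUE))
  h <- 17
  for (b in utf8ToInt(s)) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

#' Write a scenario report to disk
#'
#' Serialises a scenario result as plain-text tables: the subgroup forest
#' table and truth-group comparisons as CSV, each confusion summary as JSON,
#' the Shapley ranking and slices as CSV, excess curves as CSV, power results
#' as JSON, and always a `manifest.json` recording the master seed, derived
#' stream seeds and configuration so the run can be reproduced exactly.
#'
#' @param result A `scenario_result`, `excess_curve` or `power_result`.
#' @param dir Output directory (created if needed).
#'
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  files <- character(0)
  emit_csv <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  emit_json <- function(x, name) {
    path <- file.path(dir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    files <<- c(files, path)
  }

  if (inherits(result, "scenario_result")) {
    emit_csv(result$traditional$forest, "forest.csv")
    emit_csv(result$traditional$comparisons, "comparisons.csv")
    for (learner in names(result$ml)) {
      for (ref in c("vs_outcome", "vs_truth")) {
        cj <- confusion_to_list(result$ml[[learner]][[ref]])
        cj$learner <- learner
        cj$reference <- sub("vs_", "", ref)
        cj$omitted_variable <- result$omitted
        emit_json(cj, sprintf("confusion_%s_%s.json", learner,
                              sub("vs_", "", ref)))
      }
    }
    emit_csv(result$ranking, "ranking.csv")
    for (nm in names(result$slices)) {
      emit_csv(result$slices[[nm]]$points, sprintf("slice_%s_points.csv", nm))
      emit_csv(result$slices[[nm]]$proportions, sprintf("slice_%s_bins.csv", nm))
    }
    emit_json(list(scenario = result$scenario,
                   omitted_variable = result$omitted,
                   nnt = result$traditional$nnt,
                   detectable_effect = result$traditional$detectable,
                   provenance = result$provenance,
                   config = strip_classes(result$config)),
              "manifest.json")
  } else if (inherits(result, "excess_curve")) {
    emit_csv(as.data.frame(result), "excess_curve.csv")
    emit_json(list(scenario = "excess",
                   provenance = attr(result, "provenance")),
              "manifest.json")
  } else if (inherits(result, "power_result")) {
    emit_json(list(scenario = "power",
                   n_runs = result$n_runs,
                   n_success = result$n_success,
                   success_fraction = result$success_fraction,
                   accuracies = result$accuracies,
                   provenance = result$provenance),
              "power.json")
  } else {
    stop("unsupported result object")
  }
  invisible(files)
}
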