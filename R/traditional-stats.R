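#' Arm-level effect estimate with 95% confidence interval
#'
#' Mean difference in outcome change between treatment and placebo with a
#' z-based 95% interval using unpooled variances:
#' `mean_diff +/- 1.96 * sqrt(s_t^2/n_t + s_p^2/n_p)`.
#'
#' @param treatment_outcomes Numeric outcome changes in the treatment arm.
#' @param placebo_outcomes Numeric outcome changes in the placebo arm.
#' @param label Subgroup label for the estimate (default "overall").
#'
#' @return A one-row data frame with columns `label`, `n_treatment`,
#'   `n_placebo`, `mean_treatment`, `mean_placebo`, `mean_diff`, `ci_low`,
#'   `ci_high`.
#' @export
#' @examples
#' estimate_effect(c(12, 8), c(1, -1))
estimate_effect <- function(treatment_outcomes, placebo_outcomes,
                            label = "overall") {
  if (length(treatment_outcomes) == 0L || length(placebo_outcomes) == 0L) {
    stop("both arms must be non-empty")
  }
  n_t <- length(treatment_outcomes)
  n_p <- length(placebo_outcomes)
  diff <- mean(treatment_outcomes) - mean(placebo_outcomes)
  v_t <- if (n_t > 1L) stats::var(treatment_outcomes) else 0
  v_p <- if (n_p > 1L) stats::var(placebo_outcomes) else 0
  se <- sqrt(v_t / n_t + v_p / n_p)
  data.frame(label = label, n_treatment = n_t, n_placebo = n_p,
             mean_treatment = mean(treatment_outcomes),
             mean_placebo = mean(placebo_outcomes),
             mean_diff = diff,
             ci_low = diff - 1.96 * se,
             ci_high = diff + 1.96 * se)
}

#' Default subgroup definitions for the forest table
#'
#' Median splits for the continuous variables (age, V2, X, Y) and level
#' splits for the binary ones (sex, V1, Z). If a response rule is supplied,
#' rule-threshold splits for X and Y are appended.
#'
#' @param trial A trial data frame.
#' @param rule Optional [response_rule()] for threshold-based X/Y splits.
#'
#' @return Named list of logical patient-selection vectors.
#' @export
default_subgroups <- function(trial, rule = NULL) {
  subs <- list()
  for (v in c("age", "v2", "x", "y")) {
    med <- stats::median(trial[[v]])
    subs[[sprintf("%s <= %g", v, med)]] <- trial[[v]] <= med
    subs[[sprintf("%s > %g", v, med)]] <- trial[[v]] > med
  }
  for (v in c("sex", "v1", "z")) {
    subs[[sprintf("%s = 0", v)]] <- trial[[v]] == 0
    subs[[sprintf("%s = 1", v)]] <- trial[[v]] == 1
  }
  if (!is.null(rule)) {
    subs[[sprintf("x >= %d", rule$x_high)]] <- trial$x >= rule$x_high
    subs[[sprintf("x < %d", rule$x_high)]] <- trial$x < rule$x_high
    subs[[sprintf("y in [%d, %d]", rule$y_low, rule$y_high)]] <-
      trial$y >= rule$y_low & trial$y <= rule$y_high
    subs[[sprintf("y outside [%d, %d]", rule$y_low, rule$y_high)]] <-
      trial$y < rule$y_low | trial$y > rule$y_high
  }
  subs
}

#' Subgroup effect estimates (forest table)
#'
#' One [estimate_effect()] per subgroup, with an "overall" row first. No
#' multiplicity adjustment is applied. A subgroup with an empty arm yields a
#' row of `NA` estimates rather than an error.
#'
#' @param trial A trial data frame from [simulate_trial()].
#' @param subgroups Named list of logical vectors (or functions of the trial
#'   data frame returning logical vectors). Defaults to [default_subgroups()].
#'
#' @return A data frame of effect estimates, one row per subgroup.
#' @export
subgroup_effects <- function(trial, subgroups = NULL) {
  stopifnot(all(c("arm", "outcome_change") %in% names(trial)))
  if (is.null(subgroups)) {
    subgroups <- default_subgroups(trial, rule = attr(trial, "rule"))
  }
  treated <- trial$arm == "treatment"
  rows <- list(estimate_effect(trial$outcome_change[treated],
                               trial$outcome_change[!treated],
                               label = "overall"))
  for (lab in names(subgroups)) {
    sel <- subgroups[[lab]]
    if (is.function(sel)) sel <- sel(trial)
    stopifnot(is.logical(sel), length(sel) == nrow(trial))
    t_out <- trial$outcome_change[sel & treated]
    p_out <- trial$outcome_change[sel & !treated]
    rows[[length(rows) + 1L]] <- if (length(t_out) == 0L || length(p_out) == 0L) {
      data.frame(label = lab, n_treatment = length(t_out),
                 n_placebo = length(p_out),
                 mean_treatment = NA_real_, mean_placebo = NA_real_,
                 mean_diff = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
    } else {
      estimate_effect(t_out, p_out, label = lab)
    }
  }
  do.call(rbind, rows)
}

#' Number needed to treat
#'
#' Reciprocal of the risk difference in reaching a clinically meaningful
#' outcome change: `1 / (P(treatment >= threshold) - P(placebo >= threshold))`.
#' Returns `Inf` when the risk difference is zero or negative.
#'
#' @param treatment_outcomes,placebo_outcomes Numeric outcome changes per arm.
#' @param threshold Clinically meaningful change (default 5).
#'
#' @return A single number (possibly `Inf`).
#' @export
#' @examples
#' number_needed_to_treat(c(6, 7, 2), c(0, 1, -2))
number_needed_to_treat <- function(treatment_outcomes, placebo_outcomes,
                                   threshold = 5) {
  if (length(treatment_outcomes) == 0L || length(placebo_outcomes) == 0L) {
    stop("both arms must be non-empty")
  }
  rd <- mean(treatment_outcomes >= threshold) - mean(placebo_outcomes >= threshold)
  if (rd <= 0) Inf else 1 / rd
}

#' Compare a variable between truly responsive and non-responsive patients
#'
#' Descriptive means/SDs per ground-truth group plus a p-value: Welch's
#' two-sample t-test for continuous variables, a two-proportion z-test
#' (without continuity correction) for binary ones.
#'
#' @param trial A trial or cohort data frame with a `responsive_truth` column.
#' @param variable Name of the column to compare.
#'
#' @return A one-row data frame with columns `variable`,
#'   `mean_nonresponsive`, `sd_nonresponsive`, `mean_responsive`,
#'   `sd_responsive`, `p_value`.
#' @export
compare_by_truth <- function(trial, variable) {
  stopifnot("responsive_truth" %in% names(trial))
  if (!variable %in% names(trial)) stop("unknown variable: ", variable)
  v <- trial[[variable]]
  g1 <- v[trial$responsive_truth == 1]
  g0 <- v[trial$responsive_truth == 0]
  if (length(g1) == 0L || length(g0) == 0L) {
    stop("both truth groups must be non-empty")
  }
  binary <- all(v %in% c(0, 1))
  p <- if (binary) {
    p1 <- mean(g1); p0 <- mean(g0)
    pp <- mean(v)
    se <- sqrt(pp * (1 - pp) * (1 / length(g1) + 1 / length(g0)))
    if (se == 0) 1 else 2 * stats::pnorm(-abs((p1 - p0) / se))
  } else if (stats::sd(g1) == 0 && stats::sd(g0) == 0 && mean(g1) == mean(g0)) {
    1
  } else {
    stats::t.test(g1, g0, var.equal = FALSE)$p.value
  }
  data.frame(variable = variable,
             mean_nonresponsive = mean(g0), sd_nonresponsive = stats::sd(g0),
             mean_responsive = mean(g1), sd_responsive = stats::sd(g1),
             p_value = p)
}

#' Minimal detectable effect for a two-arm trial
#'
#' Standard normal-approximation minimal detectable difference for a
#' two-sample comparison with common standard deviation `sd`:
#' `(z_{1-alpha/2} + z_{power}) * sd * sqrt(2 / n_per_arm)`.
#'
#' @param n_per_arm Patients per arm.
#' @param power Target power (default 0.8).
#' @param alpha Two-sided significance level (default 0.05).
#' @param sd Outcome standard deviation.
#'
#' @return The minimal detectable mean difference, in outcome units.
#' @export
#' @examples
#' detectable_effect(125, sd = 3)
detectable_effect <- function(n_per_arm, power = 0.8, alpha = 0.05, sd) {
  if (power <= 0 || power >= 1) stop("power must be in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n_per_arm < 1) stop("n_per_arm must be positive")
  (stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) * sd * sqrt(2 / n_per_arm)
}
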