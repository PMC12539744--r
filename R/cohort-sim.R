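#' Treatment-response rule
#'
#' Thresholds of the deterministic rule that decides, from the phenotype
#' variables X, Y and Z, whether a patient is truly responsive to treatment.
#' A patient is responsive when any of the following holds:
#'
#' * `x >= x_high` (default 95), regardless of Y and Z;
#' * Z is present and `y_low <= y <= y_high` (default 50--90);
#' * Z is absent, `x_mid_low <= x < x_high` (default 90--94) and
#'   `y_low <= y <= y_high`.
#'
#' @param x_high X threshold above which every patient responds (default 95).
#' @param x_mid_low Lower X bound of the mid-range window that rescues
#'   Z-absent patients (default 90).
#' @param y_low,y_high Inclusive Y band within which Y supports response
#'   (defaults 50 and 90).
#'
#' @return An object of class `response_rule`.
#' @seealso [is_responsive()]
#' @export
#' @examples
#' rule <- response_rule()
#' is_responsive(96, 45, 0, rule)
response_rule <- function(x_high = 95L, x_mid_low = 90L, y_low = 50L, y_high = 90L) {
  x_high <- as.integer(x_high); x_mid_low <- as.integer(x_mid_low)
  y_low <- as.integer(y_low); y_high <- as.integer(y_high)
  if (x_mid_low >= x_high) stop("x_mid_low must be below x_high")
  if (y_low >= y_high) stop("y_low must be below y_high")
  if (x_mid_low < 50L || x_high > 100L) stop("X thresholds must lie in [50, 100]")
  if (y_low < 40L || y_high > 100L) stop("Y thresholds must lie in [40, 100]")
  structure(list(x_high = x_high, x_mid_low = x_mid_low,
                 y_low = y_low, y_high = y_high),
            class = "response_rule")
}

#' Outcome-change model
#'
#' Parameters of the trial outcome: the change in the outcome measure is drawn
#' from `N(mu_responsive, sigma)` for treated responders and from
#' `N(mu_nonresponsive, sigma)` for everyone else (placebo patients and
#' treated non-responders). A change of `clinically_meaningful_threshold` or
#' more counts as a clinically meaningful benefit.
#'
#' @param mu_responsive Mean outcome change for treated responders (default 10).
#' @param mu_nonresponsive Mean outcome change otherwise (default 0).
#' @param sigma Common standard deviation, must be non-negative (default 3).
#' @param clinically_meaningful_threshold Outcome change considered clinically
#'   meaningful (default 5); used for response labels and the NNT.
#'
#' @return An object of class `outcome_model`.
#' @export
outcome_model <- function(mu_responsive = 10, mu_nonresponsive = 0, sigma = 3,
                          clinically_meaningful_threshold = 5) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (mu_responsive <= mu_nonresponsive) {
    stop("mu_responsive must exceed mu_nonresponsive")
  }
  structure(list(mu_responsive = mu_responsive,
                 mu_nonresponsive = mu_nonresponsive,
                 sigma = sigma,
                 clinically_meaningful_threshold = clinically_meaningful_threshold),
            class = "outcome_model")
}

#' Draw a simulated clinical cohort
#'
#' Generates `n` patients with seven mutually independent phenotype variables:
#' age (integer, uniform on 18--100), sex (Bernoulli 1/2), V1 (Bernoulli 1/2),
#' V2 (integer, uniform on 0--200), X (integer, uniform on 50--100),
#' Y (integer, uniform on 40--100) and Z (Bernoulli 1/2). V1 and V2 carry no
#' information about treatment response; X, Y and Z drive the response rule.
#'
#' @param n Number of patients (>= 1).
#' @param seed Optional integer seed for reproducibility.
#'
#' @return A data frame with one row per patient and columns `patient_id`,
#'   `age`, `sex`, `v1`, `v2`, `x`, `y`, `z`.
#' @export
#' @examples
#' cohort <- draw_phenotypes(10, seed = 1)
draw_phenotypes <- function(n, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("n must be a positive integer")
  }
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    patient_id = seq_len(n),
    age = sample(18:100, n, replace = TRUE),
    sex = stats::rbinom(n, 1L, 0.5),
    v1  = stats::rbinom(n, 1L, 0.5),
    v2  = sample(0:200, n, replace = TRUE),
    x   = sample(50:100, n, replace = TRUE),
    y   = sample(40:100, n, replace = TRUE),
    z   = stats::rbinom(n, 1L, 0.5)
  )
}

#' Ground-truth treatment responsiveness
#'
#' Applies the deterministic response rule to X, Y, Z. Pure and vectorised;
#' no randomness.
#'
#' @param x,y Integer phenotype values in the declared ranges (X 50--100,
#'   Y 40--100).
#' @param z Binary phenotype (0 or 1).
#' @param rule A [response_rule()].
#'
#' @return Integer vector of 0/1 responsiveness flags.
#' @export
#' @examples
#' is_responsive(c(96, 80, 80, 92), c(45, 70, 70, 60), c(0, 1, 0, 0))
is_responsive <- function(x, y, z, rule = response_rule()) {
  stopifnot(inherits(rule, "response_rule"))
  k <- max(length(x), length(y), length(z))
  x <- rep_len(x, k); y <- rep_len(y, k); z <- rep_len(z, k)
  if (any(!is.finite(x)) || any(x < 50 | x > 100)) {
    stop("x out of range [50, 100]")
  }
  if (any(!is.finite(y)) || any(y < 40 | y > 100)) {
    stop("y out of range [40, 100]")
  }
  if (any(!z %in% c(0, 1))) stop("z must be binary (0/1)")
  y_band <- y >= rule$y_low & y <= rule$y_high
  resp <- (x >= rule$x_high) |
    (z == 1 & y_band) |
    (z == 0 & x >= rule$x_mid_low & x < rule$x_high & y_band)
  as.integer(resp)
}

#' Simulate a parallel-group randomised controlled trial
#'
#' Draws a cohort, assigns each patient independently to treatment or placebo
#' with probability 1/2 (simple randomisation, so arm sizes are random),
#' computes ground-truth responsiveness with [is_responsive()], and realises
#' the outcome change from the two-component Gaussian outcome model. Three
#' independent RNG streams (phenotypes, randomisation, outcomes) are derived
#' from the master seed, so scenario variants can hold some components fixed
#' while re-drawing others.
#'
#' @param n Number of patients (>= 2).
#' @param rule A [response_rule()].
#' @param model An [outcome_model()].
#' @param seed Optional master seed.
#'
#' @return A data frame with the cohort columns of [draw_phenotypes()] plus
#'   `arm` (factor, treatment/placebo), `responsive_truth` (0/1) and
#'   `outcome_change` (numeric). Attributes `rule`, `model` and `seeds`
#'   record the generating configuration.
#' @export
#' @examples
#' trial <- simulate_trial(200, seed = 1)
#' table(trial$arm)
simulate_trial <- function(n, rule = response_rule(), model = outcome_model(),
                           seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 2) {
    stop("n must be an integer >= 2")
  }
  if (is.null(seed)) seed <- sample.int(2147483646L, 1L)
  seeds <- derive_seeds(seed, 4L)

  cohort <- draw_phenotypes(n, seed = seeds[["phenotypes"]])

  set.seed(seeds[["randomisation"]])
  treated <- stats::rbinom(n, 1L, 0.5)
  arm <- factor(ifelse(treated == 1L, "treatment", "placebo"),
                levels = c("treatment", "placebo"))

  truth <- is_responsive(cohort$x, cohort$y, cohort$z, rule)

  set.seed(seeds[["outcomes"]])
  mu <- ifelse(arm == "treatment" & truth == 1L,
               model$mu_responsive, model$mu_nonresponsive)
  outcome <- stats::rnorm(n, mean = mu, sd = model$sigma)

  trial <- cbind(cohort,
                 data.frame(arm = arm,
                            responsive_truth = truth,
                            outcome_change = outcome))
  attr(trial, "rule") <- rule
  attr(trial, "model") <- model
  attr(trial, "seeds") <- seeds
  attr(trial, "master_seed") <- seed
  trial
}

#' Noisy-variable bank specification
#'
#' Describes a bank of uninformative covariates to append to a cohort.
#' One sixth of the bank is continuous and covaries with X (patient's X plus
#' `N(0, sd_x_noise)`), one sixth likewise with Y, one sixth is binary and
#' covaries with Z (a random `z_match_fraction` of patients copy their Z
#' value), and the remainder is fully independent, alternating between binary
#' (Bernoulli `indep_binary_prevalence`) and continuous (uniform integers on
#' `indep_continuous_range`) variables.
#'
#' @param n_noisy Number of noisy variables (>= 0).
#' @param sd_x_noise Standard deviation of the Gaussian noise added to X and
#'   Y for the linked continuous variables (default 10).
#' @param z_match_fraction Fraction of patients whose Z-linked entry copies
#'   their Z value (default 2/3).
#' @param indep_binary_prevalence Prevalence of the independent binary
#'   variables (default 0.10).
#' @param indep_continuous_range Integer range of the independent continuous
#'   variables (default `c(18, 100)`).
#' @param z_mismatch How the non-matching entries of a Z-linked variable are
#'   filled: `"flip"` (default, `1 - z`) or `"random"` (fresh Bernoulli 1/2).
#'
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(n_noisy, sd_x_noise = 10, z_match_fraction = 2 / 3,
                       indep_binary_prevalence = 0.10,
                       indep_continuous_range = c(18L, 100L),
                       z_mismatch = c("flip", "random")) {
  if (!is.numeric(n_noisy) || length(n_noisy) != 1L || n_noisy < 0) {
    stop("n_noisy must be a non-negative integer")
  }
  if (z_match_fraction <= 0 || z_match_fraction > 1) {
    stop("z_match_fraction must be in (0, 1]")
  }
  if (indep_binary_prevalence < 0 || indep_binary_prevalence > 1) {
    stop("indep_binary_prevalence must be in [0, 1]")
  }
  if (length(indep_continuous_range) != 2L ||
      indep_continuous_range[1] >= indep_continuous_range[2]) {
    stop("indep_continuous_range must be an increasing integer pair")
  }
  structure(list(n_noisy = as.integer(n_noisy),
                 sd_x_noise = sd_x_noise,
                 z_match_fraction = z_match_fraction,
                 indep_binary_prevalence = indep_binary_prevalence,
                 indep_continuous_range = as.integer(indep_continuous_range),
                 z_mismatch = match.arg(z_mismatch)),
            class = "noise_spec")
}

#' Append noisy variables to a cohort
#'
#' Adds `spec$n_noisy` uninformative variables according to the class recipe
#' of [noise_spec()]. Class sizes use `floor(n_noisy / 6)` for each of the
#' X-, Y- and Z-linked classes, with the remainder going to the independent
#' class; variables are laid out in that fixed index order and named
#' `n0001, n0002, ...`. Within the independent block, variables alternate
#' binary, continuous, binary, ... by index.
#'
#' @param cohort A cohort or trial data frame containing columns `x`, `y`, `z`.
#' @param spec A [noise_spec()].
#' @param seed Optional seed for the noise stream.
#'
#' @return The cohort with the noisy columns appended; existing columns and
#'   attributes are untouched.
#' @export
#' @examples
#' cohort <- draw_phenotypes(50, seed = 1)
#' wide <- add_noise_variables(cohort, noise_spec(6), seed = 2)
#' setdiff(names(wide), names(cohort))
add_noise_variables <- function(cohort, spec, seed = NULL) {
  stopifnot(is.data.frame(cohort), inherits(spec, "noise_spec"))
  if (spec$n_noisy == 0L) return(cohort)
  if (!all(c("x", "y", "z") %in% names(cohort))) {
    stop("cohort must contain columns x, y, z")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort)
  m <- spec$n_noisy
  k <- m %/% 6L                    # per linked class
  n_indep <- m - 3L * k            # remainder is independent

  out <- matrix(0, nrow = n, ncol = m)
  col <- 0L
  for (i in seq_len(k)) {          # X-linked continuous
    col <- col + 1L
    out[, col] <- cohort$x + stats::rnorm(n, 0, spec$sd_x_noise)
  }
  for (i in seq_len(k)) {          # Y-linked continuous
    col <- col + 1L
    out[, col] <- cohort$y + stats::rnorm(n, 0, spec$sd_x_noise)
  }
  n_match <- as.integer(round(spec$z_match_fraction * n))
  for (i in seq_len(k)) {          # Z-linked binary
    col <- col + 1L
    v <- if (spec$z_mismatch == "flip") {
      1L - cohort$z
    } else {
      stats::rbinom(n, 1L, 0.5)
    }
    sel <- sample.int(n, n_match)
    v[sel] <- cohort$z[sel]
    out[, col] <- v
  }
  rng <- spec$indep_continuous_range
  for (i in seq_len(n_indep)) {    # independent, alternating binary/continuous
    col <- col + 1L
    out[, col] <- if (i %% 2L == 1L) {
      stats::rbinom(n, 1L, spec$indep_binary_prevalence)
    } else {
      sample(rng[1]:rng[2], n, replace = TRUE)
    }
  }
  width <- max(4L, nchar(as.character(m)))
  colnames(out) <- sprintf(paste0("n%0", width, "d"), seq_len(m))

  res <- cbind(cohort, as.data.frame(out))
  for (a in c("rule", "model", "seeds", "master_seed")) {
    attr(res, a) <- attr(cohort, a)
  }
  attr(res, "noise_spec") <- spec
  res
}

#' Remove a variable from a cohort
#'
#' Drops one named column (e.g. to model a covariate that was never
#' collected). All other values are untouched and the input is not modified.
#'
#' @param cohort A cohort or trial data frame.
#' @param name Name of the column to drop.
#'
#' @return The cohort without the named column.
#' @export
remove_variable <- function(cohort, name) {
  stopifnot(is.data.frame(cohort), is.character(name), length(name) == 1L)
  if (!name %in% names(cohort)) {
    stop("variable not found in cohort: ", name)
  }
  res <- cohort[setdiff(names(cohort), name)]
  for (a in c("rule", "model", "seeds", "master_seed", "noise_spec")) {
    attr(res, a) <- attr(cohort, a)
  }
  res
}

#' Write a trial table and its provenance sidecar
#'
#' Serialises a simulated trial as CSV (one row per patient) together with a
#' JSON sidecar recording the master seed, stream seeds, response rule and
#' outcome model, so the trial can be regenerated exactly.
#'
#' @param trial A data frame from [simulate_trial()].
#' @param path Output CSV path; the sidecar is written next to it with
#'   extension `.json`.
#'
#' @return Invisibly, the paths written.
#' @export
write_trial <- function(trial, path) {
  utils::write.csv(trial, path, row.names = FALSE)
  sidecar <- sub("\\.csv$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  meta <- list(
    master_seed = attr(trial, "master_seed"),
    seeds = as.list(attr(trial, "seeds")),
    rule = unclass(attr(trial, "rule")),
    model = unclass(attr(trial, "model")),
    noise_spec = if (!is.null(attr(trial, "noise_spec"))) {
      unclass(attr(trial, "noise_spec"))
    },
    n_patients = nrow(trial)
  )
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(csv = path, json = sidecar))
}
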