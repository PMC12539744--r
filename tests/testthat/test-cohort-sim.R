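test_that("response rule matches the exhaustive enumeration oracle", {
  g <- oracle_grid()
  got <- is_responsive(g$x, g$y, g$z)
  expect_identical(got, as.integer(g$responsive))
  expect_equal(mean(got), 2782 / 6222, tolerance = 1e-12)
})

test_that("response rule handles its edge cases and validates inputs", {
  expect_identical(is_responsive(96, 45, 0), 1L)  # high X alone suffices
  expect_identical(is_responsive(95, 40, 0), 1L)  # threshold is inclusive
  expect_identical(is_responsive(80, 70, 1), 1L)  # Z rescues mid Y
  expect_identical(is_responsive(80, 70, 0), 0L)
  expect_identical(is_responsive(92, 60, 0), 1L)  # mid-X window, Z absent
  expect_identical(is_responsive(c(94, 90, 89), c(90, 50, 60), 0), c(1L, 1L, 0L))

  expect_error(is_responsive(49, 60, 0), "out of range")
  expect_error(is_responsive(96, 101, 0), "out of range")
  expect_error(is_responsive(96, 60, 2), "binary")
  expect_error(response_rule(x_high = 90, x_mid_low = 95), "x_mid_low")
  expect_error(response_rule(y_low = 90, y_high = 50), "y_low")
})

test_that("phenotype draws respect ranges, marginals and determinism", {
  n <- 20000
  cohort <- draw_phenotypes(n, seed = 3)
  expect_equal(nrow(cohort), n)
  expect_true(all(cohort$age >= 18 & cohort$age <= 100))
  expect_true(all(cohort$v2 >= 0 & cohort$v2 <= 200))
  expect_true(all(cohort$x >= 50 & cohort$x <= 100))
  expect_true(all(cohort$y >= 40 & cohort$y <= 100))
  expect_true(all(cohort$sex %in% 0:1) && all(cohort$v1 %in% 0:1) &&
                all(cohort$z %in% 0:1))

  # exact discrete uniform moments: mean 75, sd sqrt((51^2 - 1) / 12)
  se_x <- sqrt((51^2 - 1) / 12) / sqrt(n)
  expect_lt(abs(mean(cohort$x) - 75), 3 * se_x)

  expect_identical(draw_phenotypes(5, seed = 11), draw_phenotypes(5, seed = 11))
  expect_false(identical(draw_phenotypes(5, seed = 11),
                         draw_phenotypes(5, seed = 12)))
  expect_error(draw_phenotypes(0), "positive")
})

test_that("trial assembly: simple randomisation, outcome mixture, determinism", {
  counts <- vapply(1:20, function(s) {
    sum(simulate_trial(1000, seed = s)$arm == "treatment")
  }, numeric(1))
  # 99.98% central interval of Binomial(1000, 1/2)
  expect_true(all(counts >= qbinom(1e-4, 1000, 0.5) &
                    counts <= qbinom(1 - 1e-4, 1000, 0.5)))

  trial <- simulate_trial(4000, seed = 1)
  tr_resp <- trial$arm == "treatment" & trial$responsive_truth == 1
  k <- sum(tr_resp)
  expect_lt(abs(mean(trial$outcome_change[tr_resp]) - 10), 3 * 3 / sqrt(k))
  expect_lt(abs(mean(trial$outcome_change[!tr_resp])), 3 * 3 / sqrt(4000 - k))
  expect_identical(trial$responsive_truth,
                   is_responsive(trial$x, trial$y, trial$z))

  noiseless <- simulate_trial(500, model = outcome_model(sigma = 0), seed = 2)
  tr_resp <- noiseless$arm == "treatment" & noiseless$responsive_truth == 1
  expect_true(all(noiseless$outcome_change[tr_resp] == 10))
  expect_true(all(noiseless$outcome_change[!tr_resp] == 0))

  expect_identical(simulate_trial(100, seed = 9), simulate_trial(100, seed = 9))
  expect_error(simulate_trial(1), ">= 2")
})

test_that("noise bank honours class layout, covariance recipes and determinism", {
  cohort <- draw_phenotypes(4000, seed = 5)
  expect_identical(add_noise_variables(cohort, noise_spec(0)), cohort)

  wide <- add_noise_variables(cohort, noise_spec(6), seed = 8)
  new_cols <- setdiff(names(wide), names(cohort))
  expect_identical(new_cols, sprintf("n%04d", 1:6))

  # closed form: cor(X + N(0, 10), X) = sd_x / sqrt(sd_x^2 + 100)
  sd_x2 <- (51^2 - 1) / 12
  expect_equal(cor(wide$n0001, wide$x), sqrt(sd_x2 / (sd_x2 + 100)),
               tolerance = 0.03)
  sd_y2 <- (61^2 - 1) / 12
  expect_equal(cor(wide$n0002, wide$y), sqrt(sd_y2 / (sd_y2 + 100)),
               tolerance = 0.03)

  # Z-linked: exactly round(2/3 n) entries agree with Z under the flip default
  expect_true(all(wide$n0003 %in% 0:1))
  expect_identical(sum(wide$n0003 == wide$z), as.integer(round(2 / 3 * 4000)))

  # independent remainder alternates binary / continuous / binary
  expect_true(all(wide$n0004 %in% 0:1))
  expect_lt(abs(mean(wide$n0004) - 0.10), 0.02)
  expect_true(all(wide$n0005 >= 18 & wide$n0005 <= 100))
  expect_true(all(wide$n0006 %in% 0:1))
  for (v in c("n0004", "n0005", "n0006")) {
    expect_lt(max(abs(cor(wide[[v]], cohort[, c("x", "y", "z")]))), 0.1)
  }

  expect_identical(add_noise_variables(cohort, noise_spec(6), seed = 8), wide)
  expect_error(noise_spec(-1), "non-negative")
})

test_that("remove_variable drops exactly one column and round-trips", {
  cohort <- draw_phenotypes(50, seed = 1)
  kept <- cohort$z
  reduced <- remove_variable(cohort, "z")
  expect_false("z" %in% names(reduced))
  expect_identical(reduced[names(reduced)], cohort[names(reduced)])
  expect_identical(ncol(reduced), ncol(cohort) - 1L)

  restored <- cbind(reduced, z = kept)[names(cohort)]
  expect_identical(restored$z, cohort$z)
  expect_true("z" %in% names(cohort))  # input untouched
  expect_error(remove_variable(cohort, "q"), "not found")
})

test_that("trial serialisation writes the table and a provenance sidecar", {
  trial <- simulate_trial(30, seed = 4)
  path <- file.path(tempdir(), "trial.csv")
  files <- write_trial(trial, path)
  expect_true(all(file.exists(files)))
  back <- read.csv(path)
  expect_equal(back$outcome_change, trial$outcome_change, tolerance = 1e-9)
  meta <- jsonlite::read_json(files[["json"]])
  expect_equal(meta$master_seed, 4)
  expect_equal(meta$rule$x_high, 95)
  expect_equal(meta$n_patients, 30)
})
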