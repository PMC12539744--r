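test_that("outcome binarisation thresholds at the clinical cutoff", {
  expect_identical(binarize_outcome(c(5, 4.999, -2, 11)), c(1L, 0L, 0L, 1L))
  expect_identical(binarize_outcome(rep(0, 4)), rep(0L, 4))
  expect_identical(binarize_outcome(c(2, 3), threshold = 2.5), c(0L, 1L))
  expect_error(binarize_outcome(c(1, NA)), "finite")
  expect_error(binarize_outcome(c(1, Inf)), "finite")
})

test_that("standardize centres continuous columns with fit-row statistics only", {
  set.seed(2)
  m <- cbind(cont = rnorm(100, 5, 2), bin = rbinom(100, 1, 0.3))
  fit_rows <- 1:60
  s <- standardize(m, fit_rows = fit_rows)
  expect_equal(mean(s[fit_rows, "cont"]), 0, tolerance = 1e-12)
  expect_equal(sd(s[fit_rows, "cont"]), 1, tolerance = 1e-12)
  expect_identical(s[, "bin"], m[, "bin"])  # binary pass-through
  # held-out rows transformed with the same (fit-row) statistics
  expect_equal(s[61:100, "cont"],
               (m[61:100, "cont"] - mean(m[fit_rows, "cont"])) /
                 sd(m[fit_rows, "cont"]))

  m2 <- cbind(const = rep(3, 10), ok = rnorm(10))
  expect_warning(s2 <- standardize(m2), "constant")
  expect_identical(s2[, "const"], m2[, "const"])
  expect_error(standardize(m, fit_rows = integer(0)), "non-empty")
})

test_that("out-of-fold accounting: one prediction per patient, balanced folds", {
  set.seed(3)
  feats <- cbind(a = rnorm(23), b = rnorm(23))
  labels <- rbinom(23, 1, 0.5)
  fit <- oof_predict(feats, labels, boost_params(n_rounds = 5), k_folds = 5,
                     seed = 1)
  expect_identical(sort(fit$predictions$patient_id), 1:23)
  expect_true(all(table(fit$predictions$fold) %in% 4:5))

  # leave-one-out: n single-row predictions
  loo <- oof_predict(cbind(a = rnorm(10)), rep(0:1, 5),
                     boost_params(n_rounds = 2), k_folds = 10, seed = 1)
  expect_identical(nrow(loo$predictions), 10L)
  expect_identical(sort(unique(loo$predictions$fold)), 1:10)

  expect_error(oof_predict(feats, labels, boost_params(), k_folds = 24),
               "k_folds")
  expect_error(oof_predict(feats, rep(0L, 23), boost_params()),
               "both classes")
  expect_error(oof_predict(feats, labels, list()), "model_params")
})

test_that("a training fold with a single class fails loudly, naming the fold", {
  feats <- cbind(a = rnorm(10))
  labels <- c(rep(0L, 9), 1L)
  expect_error(oof_predict(feats, labels, boost_params(n_rounds = 2),
                           k_folds = 2, seed = 1),
               "fold [12]")
})

test_that("boosted learner recovers a single-threshold concept out of fold", {
  set.seed(9)
  x <- sample(50:100, 200, replace = TRUE)
  feats <- cbind(x = x, noise1 = rnorm(200), noise2 = rnorm(200))
  labels <- as.integer(x >= 95)
  fit <- oof_predict(feats, labels, boost_params(), seed = 2)
  expect_gte(mean(fit$predictions$predicted_label == labels), 0.95)

  # deterministic under a fixed seed, seed-sensitive otherwise
  fit2 <- oof_predict(feats, labels, boost_params(), seed = 2)
  expect_identical(fit$predictions, fit2$predictions)
  fit3 <- oof_predict(feats, labels, boost_params(), seed = 3)
  expect_false(identical(fit$predictions$prob, fit3$predictions$prob))
})

test_that("logistic comparator needs its pairwise interactions for products", {
  set.seed(12)
  n <- 400
  feats <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  labels <- as.integer(feats[, "a"] * feats[, "b"] > 0)  # pure interaction
  with_int <- oof_predict(feats, labels, logistic_params(), seed = 5)
  without <- oof_predict(feats, labels,
                         logistic_params(include_pairwise_interactions = FALSE),
                         seed = 5)
  expect_gte(mean(with_int$predictions$predicted_label == labels), 0.85)
  expect_lte(mean(without$predictions$predicted_label == labels), 0.65)
})

test_that("confusion summary counts, rates and id matching", {
  pred <- data.frame(patient_id = 1:5, predicted_label = c(1L, 1L, 0L, 0L, 1L))
  ref <- c(1L, 0L, 0L, 1L, 1L)
  cs <- evaluate(pred, ref)
  expect_identical(c(cs$tp, cs$fp, cs$fn, cs$tn), c(2L, 1L, 1L, 1L))
  expect_equal(cs$accuracy, 3 / 5)
  expect_equal(cs$sensitivity, 2 / 3)
  expect_equal(cs$specificity, 1 / 2)
  expect_equal(cs$ppv, 2 / 3)
  expect_equal(cs$npv, 1 / 2)

  # named references are matched by patient id, order-independently
  named <- setNames(ref, 1:5)[c(3, 1, 5, 2, 4)]
  expect_equal(evaluate(pred, named)$accuracy, cs$accuracy)

  perfect <- evaluate(pred, pred$predicted_label)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$sensitivity, 1)
  inverted <- evaluate(pred, 1L - pred$predicted_label)
  expect_equal(inverted$accuracy, 0)

  expect_error(evaluate(pred, ref[1:3]), "match")
  expect_error(evaluate(pred, setNames(ref, 2:6)), "missing")
})

test_that("binomial-normal accuracy CI reproduces printed intervals", {
  expect_equal(round(accuracy_ci(498, 509), 3), c(0.966, 0.991))
  expect_equal(round(accuracy_ci(353, 509), 3), c(0.653, 0.734))
  expect_identical(accuracy_ci(509, 509), c(1, 1))  # degenerate, clipped
  expect_identical(accuracy_ci(0, 10)[1], 0)
  expect_error(accuracy_ci(5, 0), "total")
  expect_error(accuracy_ci(11, 10), "correct")
})
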