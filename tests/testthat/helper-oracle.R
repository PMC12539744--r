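# Independent brute-force oracle for the treatment-response rule, written as
# a literal scalar transcription of the verbal rule (kept deliberately
# separate from the vectorised package implementation it checks).
oracle_responsive_one <- function(x, y, z) {
  if (x >= 95) return(1L)
  if (z == 1 && y >= 50 && y <= 90) return(1L)
  if (z == 0 && x >= 90 && x <= 94 && y >= 50 && y <= 90) return(1L)
  0L
}

# Exhaustive enumeration over the 51 x 61 x 2 integer grid of (X, Y, Z).
oracle_grid <- function() {
  g <- expand.grid(x = 50:100, y = 40:100, z = 0:1)
  g$responsive <- mapply(oracle_responsive_one, g$x, g$y, g$z)
  g
}

# Conditional moments of the grid, used as analytic expectations in tests.
oracle_stats <- function() {
  g <- oracle_grid()
  r <- g$responsive == 1
  list(
    frac_responsive = mean(r),
    p_z_given_resp = mean(g$z[r]),
    p_z_given_nonresp = mean(g$z[!r]),
    mean_x_resp = mean(g$x[r]),
    mean_x_nonresp = mean(g$x[!r]),
    frac_resp_z1 = mean(g$responsive[g$z == 1]),
    frac_resp_z0 = mean(g$responsive[g$z == 0])
  )
}

# Small baseline boosted fit on the treatment arm of a simulated trial,
# shared by the interpretability tests.
make_baseline_fit <- function(n = 1000, seed = 7, drop = NULL,
                              params = boost_params()) {
  trial <- simulate_trial(n, seed = seed)
  treated <- trial[trial$arm == "treatment", ]
  feats <- treated[, c("age", "sex", "v1", "v2", "x", "y", "z")]
  if (!is.null(drop)) feats <- feats[, setdiff(names(feats), drop)]
  labels <- binarize_outcome(treated$outcome_change)
  list(trial = trial,
       treated = treated,
       fit = oof_predict(feats, labels, params, seed = seed + 1,
                         patient_ids = treated$patient_id))
}
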