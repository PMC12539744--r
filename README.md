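# phenosim

Simulated randomised controlled trials (RCTs) with a known, non-linear link
between clinical phenotype and treatment response — built to contrast what a
traditional arm-level analysis concludes with what a cross-validated
gradient-boosted classifier can recover about *individual* treatment
response, and to probe how that recovery degrades when phenotyping is
incomplete (a missing covariate) or excessive (thousands of noise
covariates).

It is aimed at biostatisticians and clinical-research methodologists who want
a fully specified, reproducible test bed where ground truth is known by
construction.

## The model

Each of *n* patients carries seven independent phenotype variables:

| variable | distribution |
|---|---|
| age | integer uniform on [18, 100] |
| sex, V1, Z | Bernoulli(1/2) |
| V2 | integer uniform on [0, 200] |
| X | integer uniform on [50, 100] |
| Y | integer uniform on [40, 100] |

A deterministic rule defines true responsiveness R ∈ {0, 1}:

    R = 1  iff  X ≥ 95
            or  (Z = 1 and 50 ≤ Y ≤ 90)
            or  (Z = 0 and 90 ≤ X ≤ 94 and 50 ≤ Y ≤ 90)

Exhaustive enumeration of the 51 × 61 × 2 grid gives
P(R = 1) = 2782/6222 ≈ 0.4471. Patients are randomised 1:1 (simple
per-patient randomisation), and the outcome change is

    ΔO ~ N(10, 3²)  for treated responders,
    ΔO ~ N(0, 3²)   otherwise,

with ΔO ≥ 5 taken as clinically meaningful. Age, sex, V1 and V2 never enter
the rule. The traditional analysis (difference in arm means with a z-based
95% CI, subgroup forest table, number needed to treat) sees a clear average
benefit; the per-patient structure is only visible to a classifier. The ML
arm fits an XGBoost binary classifier (depth 3, learning rate 0.1,
100 rounds, 80% row/feature subsampling) with 5-fold out-of-fold prediction
on the treatment arm, using the noisy ΔO ≥ 5 labels for training and the
latent R only for evaluation, plus a ridge-logistic comparator with all
pairwise interactions. Fitted models are interrogated with exact tree-path
Shapley (SHAP) attributions.

## Worked example

```r
library(phenosim)

trial <- simulate_trial(1000, seed = 1)
table(trial$arm)
#> treatment   placebo
#>       492       508
mean(trial$responsive_truth)
#> [1] 0.448

tr <- trial$arm == "treatment"
estimate_effect(trial$outcome_change[tr], trial$outcome_change[!tr])
#>     label n_treatment n_placebo mean_treatment mean_placebo mean_diff ci_low ci_high
#> 1 overall         492       508           4.93       0.0481      4.88    4.3    5.46
number_needed_to_treat(trial$outcome_change[tr], trial$outcome_change[!tr])
#> [1] 2.33
```

The traditional readout: a mean benefit of ≈4.9 outcome units (95% CI
4.3–5.5) and an NNT of ≈2.3 — the treatment looks good for everyone, even
though 55% of this cohort cannot respond. The ML arm sees the individuals:

```r
treated <- trial[tr, ]
feats  <- treated[, c("age", "sex", "v1", "v2", "x", "y", "z")]
labels <- binarize_outcome(treated$outcome_change)
fit <- oof_predict(feats, labels, boost_params(), seed = 2,
                   patient_ids = treated$patient_id)
evaluate(fit, treated$responsive_truth)
#> confusion summary (n = 492)
#>           ref 1  ref 0
#>   pred 1    230      6
#>   pred 0      3    253
#>   accuracy 0.982 (95% CI 0.970-0.994)
#>   sens 0.987  spec 0.977  ppv 0.975  npv 0.988

rank_features(attribute(fit))
#>   feature importance
#> 1       y      773.9
#> 2       z      690.9
#> 3       x      603.7
#> 4      v2      101.7
#> 5     age       88.1
#> 6     sex       19.8
#> 7      v1       14.9
```

Out-of-fold, the boosted model identifies true responders with 98.2%
accuracy, and the Shapley ranking singles out exactly the three
response-determining variables (X, Y, Z) over the uninformative ones.
Dropping Z before training — the same patients, one variable not collected —
collapses ground-truth accuracy to 73%:

```r
fit_z <- oof_predict(remove_variable(feats, "z"), labels, boost_params(),
                     seed = 2, patient_ids = treated$patient_id)
evaluate(fit_z, treated$responsive_truth)$accuracy
#> [1] 0.732
```

Scenario drivers (`run_baseline()`, `run_deficiency()`, `run_excess()`,
`run_power()`) wrap the full pipelines and `write_report()` serialises every
table as CSV/JSON with a provenance manifest. A thin command-line wrapper
lives at `inst/scripts/phenosim.R`:

```sh
Rscript inst/scripts/phenosim.R --scenario baseline --n 1000 --seed 1 --out results/
```

See `vignettes/simulated-trial-ml.Rmd` for the methods account: modelling
assumptions, parameter choices, numerical decisions and limitations.

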