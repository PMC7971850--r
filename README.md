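# mrkit

Two-sample Mendelian randomization (MR) from GWAS summary statistics, as an
R package. `mrkit` is aimed at genetic epidemiologists who want to screen
many exposures against one or more disease outcomes using only published
association summary statistics — for example, cardiometabolic traits against
infectious-disease severity — with the full standard battery of instrument
diagnostics and pleiotropy sensitivity analyses, plus a summary-statistic
simulator with known causal truth for validating every step.

## What it computes

Given per-variant association estimates for an exposure X and an outcome Y
(effect alleles, effect sizes `beta`, standard errors `se`, p-values,
allele frequencies), `mrkit` implements:

* **Instrument selection** — genome-wide-significance filtering
  (`p < 5e-8`), greedy LD clumping (drop variants with `r² > 0.01` to, or
  within 1 Mb of, a better-associated variant), per-variant F-statistics
  (`(beta/se)²`, with the conventional F < 10 weak-instrument flag) and
  variance explained (F-quantile inversion for continuous traits, a
  liability-threshold approximation for binary ones).
* **Harmonization** — aligning the outcome to the exposure's effect allele,
  resolving strand flips, and excluding strand-ambiguous palindromic (A/T,
  C/G) variants whose allele frequency lies in [0.4, 0.6].
* **Causal estimators** — for aligned effect pairs (β_Xj, β_Yj) with
  outcome weights w_j = 1/se²_Yj:
  - IVW: `θ̂ = Σ w β_X β_Y / Σ w β_X²`, fixed-effect
    `se = (Σ w β_X²)^(-1/2)`, random-effects inflation
    `max(1, √(Q/(k−1)))` with Cochran's `Q = Σ w (β_Y − θ̂ β_X)²`;
  - MR-Egger: weighted regression with a free intercept; the intercept
    tests directional pleiotropy;
  - weighted median and mode-based estimators with seeded parametric
    bootstrap standard errors;
  - leave-one-out refits and **MR-PRESSO** (global residual-sum test,
    per-variant outlier test, distortion test, all by parametric
    resampling).
* **Multivariable MR** — joint weighted regression of β_Y on several
  exposures' β_X columns (direct/conditional effects), with the conditional
  instrument-strength Q statistic for weak-instrument diagnosis.
* **Screening pipeline** — exposures × outcomes with Bonferroni control
  (`alpha / (n_exposures × n_outcomes)`), direction-concordance indicators
  across methods, and a `detectable_or()` power diagnostic.
* **Simulator** — paired (or multi-exposure, with mediation paths)
  summary statistics with configurable causal effect, pleiotropy regime,
  instrument strength and case/control imbalance, all from one seed.

## Worked example

Simulate a BMI-like exposure (50 instruments explaining ~2% of variance,
GWAS n ≈ 339k) against a rare binary outcome (6,406 cases / 902,088
controls) with a true effect of 0.10 log-odds per SD, then run the standard
analysis:

```r
library(mrkit)

sim  <- simulate_gwas_pair(sim_config(theta = 0.10, seed = 7,
                                      exposure_id = "bmi",
                                      outcome_id = "covid_hosp"))
iset <- ld_clump(select_candidates(sim$exposure, 5e-8))
iset
#> <instrument_set> trait: bmi - 41 instruments
#>   F-statistic: median 134 | weak (F < 10): 0
#>   variance explained (sum): 0.0188

dat <- harmonize_dataset(iset, sim$outcome)
ivw <- mr_ivw(dat, "random")
ivw
#> <mr_estimate> ivw_re: beta = 0.1429 (se 0.04567), 95% CI [0.05338, 0.2324], p = 0.001756, k = 41
#>   Cochran Q = 38 (p = 0.5608)
exp(c(ivw$beta, ivw$ci_low, ivw$ci_high))   # OR per SD: 1.154 [1.055, 1.262]

mr_egger(dat)
#> <mr_estimate> egger: beta = 0.2984 (se 0.119), 95% CI [0.05764, 0.5392], p = 0.01646, k = 41
#>   Cochran Q = 36 (p = 0.6077)
#>   Egger intercept = -0.006251 (se 0.004418, p = 0.1651)

run_presso(dat, n_sim = 2000, seed = 2)
#> <mr_presso_result> global RSS = 39.65, p = 0.5607 (2000 simulations)
#>   no outlying variants at adjusted p < 0.05

bonferroni_threshold(17, 2, 0.05)$display
#> [1] "0.0015"
```

Reading: 41 of the 50 simulated instruments reach genome-wide significance
and survive clumping; the IVW odds ratio per SD of exposure is 1.154 (95%
CI 1.055–1.262), Cochran's Q shows no heterogeneity (p = 0.56), the Egger
intercept shows no directional pleiotropy (p = 0.17), and MR-PRESSO flags
no outlying variants. Against a 17-exposure × 2-outcome Bonferroni
threshold of 0.0015, p = 0.0018 would just miss the significance bar —
exactly the kind of borderline call the screen is designed to adjudicate.

For multivariable MR with a mediator, see `simulate_multi_exposure()`,
`build_mvmr_dataset()` and `mvmr_fit()`; for many-pair screens, see
`run_screen()`. The methods vignette (`vignettes/mr-methods.Rmd`) documents
the statistical conventions and design choices.

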