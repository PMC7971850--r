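---
title: "Methods and design choices in mrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in mrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrkit)
```

## The model

Two-sample Mendelian randomization treats genetic variants as instrumental
variables for a modifiable exposure. For variant $j$, let $\beta_{Xj}$ and
$\beta_{Yj}$ be its estimated effects on the exposure and on the outcome
(from two non-overlapping GWAS samples), with standard errors $se_{Xj}$ and
$se_{Yj}$. If variant $j$ is a valid instrument — associated with the
exposure, independent of confounders, and affecting the outcome only
through the exposure — then $\beta_{Yj} \approx \theta\, \beta_{Xj}$, where
$\theta$ is the causal effect. Every estimator in `mrkit` is a different
way of pooling the per-variant Wald ratios
$\hat\theta_j = \beta_{Yj}/\beta_{Xj}$ under different assumptions about
which instruments are valid:

* **IVW** (`mr_ivw`) assumes all instruments valid: a weighted regression
  of $\beta_Y$ on $\beta_X$ through the origin with weights
  $w_j = 1/se_{Yj}^2$. The random-effects variant (the package's primary
  estimator) inflates the fixed-effect standard error by
  $\max(1, \sqrt{Q/(k-1)})$ — the multiplicative overdispersion model with
  a floor at one, so heterogeneity widens intervals but apparent
  underdispersion never narrows them.
* **MR-Egger** (`mr_egger`) frees the intercept; under the InSIDE
  assumption (pleiotropic effects independent of instrument strength) the
  slope remains consistent even when all instruments are pleiotropic, and
  the intercept estimates the average directional pleiotropy. Inference
  uses Student's t with $k-2$ degrees of freedom, the small-sample
  convention for this estimator; all other methods use normal quantiles.
* **Weighted median** (`mr_weighted_median`) is consistent when valid
  instruments carry at least half the total weight: the weighted quantile
  function of the ordered ratios, evaluated by linear interpolation of the
  cumulative weights $p_j = (S_j - w_j/2)/S_\mathrm{tot}$ at $1/2$.
* **Mode-based estimator** (`mr_mode`) is consistent when the largest
  cluster of similar ratios is valid: the argmax of a Gaussian-kernel
  density over ratios, weighted by inverse ratio variance.
* **MR-PRESSO** (`run_presso`) tests for and removes outlying variants via
  the leave-one-out residual sum of squares, with an empirical null built
  by parametric resampling of the summary statistics.
* **Multivariable MR** (`mvmr_fit`) regresses $\beta_Y$ jointly on several
  exposures' effect columns (no intercept, weights $1/se_Y^2$), giving each
  exposure's *direct* effect conditional on the others — the tool used to
  ask whether one exposure's apparent effect is mediated by another.

Per-variant ratio variances use the first-order delta method
($se_{Yj}^2/\beta_{Xj}^2$), the summary-data MR convention; exposure-side
noise enters only at second order and is ignored in the weights.

## Instrument selection and harmonization

Candidates are variants with exposure $p <$ `p_threshold` (default
$5\times10^{-8}$). Clumping is greedy: sort by ascending p-value — ties
broken by chromosome, position, then variant id, so the result is
invariant to input row order — accept the best remaining variant, discard
every remaining variant with $r^2 >$ `r2_threshold` (default 0.01; 0.001
is a one-argument sensitivity change) to an accepted variant *or* within
`window_bp` (default 1 Mb, center-to-center, half-open, 1-based) of one on
the same chromosome. Variants absent from the LD source are treated as
unlinked with a warning, so pruning degrades gracefully to the distance
rule; the explicit `ld_source_empty()` declares independence and stays
quiet.

Harmonization aligns the outcome record to the exposure's effect allele,
complementing strands for non-palindromic single-nucleotide pairs and
comparing indel alleles as exact strings. Palindromic pairs (A/T, C/G)
carry no strand information in their allele labels, so orientation rests
entirely on allele frequency: within the ambiguity window `af_window`
(default [0.4, 0.6], applied to *either* dataset's frequency — the
conservative reading) the variant is excluded; outside it, orientation is
by minor/major frequency matching, and a missing frequency also excludes
(conservative, since nothing identifies the strand). Palindrome exclusion
is applied in univariable and multivariable analyses alike by default —
it is stated as a multivariable step in some study protocols, but there is
no reason the ambiguity is less damaging univariably — and can be disabled
with `palindrome_filter = FALSE`.

## Variance explained and instrument strength

For continuous traits, per-variant variance explained inverts the
association p-value to an F quantile on $(1, n-2)$ degrees of freedom and
returns $r^2 = F/(F+n-2)$. For binary traits the package uses the
liability-threshold approximation: with prevalence $K$ (default: the
sample case fraction), threshold $t = \Phi^{-1}(1-K)$ and $z = \phi(t)$,
a per-allele log odds ratio maps to a liability effect
$\beta_\ell \approx \log\mathrm{OR} \cdot K(1-K)/z$, giving
$r^2_\ell = 2f(1-f)\beta_\ell^2$. This is one of several defensible
observed-to-liability conversions; it is exact in the small-effect limit,
is symmetric under allele relabeling, and is validated in the test suite
by a round-trip simulation that recovers a known liability heritability
(after subtracting the analytic sampling-noise inflation
$\sum_j c_j\,se_j^2$).

The conditional instrument-strength statistic (`instrument_strength_q`)
regresses the target exposure's variant effects on the other exposures'
effects (precision-weighted, with intercept) and refers the weighted
residual sum to $\chi^2_{k-m}$: large Q means the instruments predict the
target beyond what they share with the other exposures; residuals near
zero flag conditionally weak instruments. Exposure columns that are
identically zero are dropped from the multivariable solve (their
conditional effect is unidentified and reported as `NA`), which makes a
two-exposure fit with one null column reduce exactly to univariable IVW;
*near*-collinear columns (condition number above $10^{10}$) raise a
diagnostic error instead, because a silently unstable solve is worse than
no answer.

## MR-PRESSO details

The observed statistic is
$\mathrm{RSS} = \sum_j w_j(\beta_{Yj} - \hat\theta_{(-j)}\beta_{Xj})^2$
with $\hat\theta_{(-j)}$ the leave-one-out IVW slope. The null is built by
drawing $\beta^*_{Xj} \sim N(\beta_{Xj}, se_{Xj})$ and
$\beta^*_{Yj} \sim N(\hat\theta_{(-j)}\beta_{Xj}, se_{Yj})$ for `n_sim`
replicates and recomputing RSS identically. All empirical p-values use the
$(r+1)/(n_\mathrm{sim}+1)$ estimator, so none is exactly zero. Per-variant
outlier p-values are Bonferroni-corrected across the $k$ tested variants;
a flagged set triggers the distortion test, implemented here as the
displacement between the full and outlier-removed IVW slopes compared with
the same-index displacement in each null replicate (a deterministic
variant of the classical inlier-resampling construction — same question,
reproducible answer). The corrected estimate is plain random-effects IVW
on the remaining variants.

Two behaviors are worth knowing. First, Bonferroni flagging at
significance 0.05 has, by construction, roughly a 5% per-dataset chance of
co-flagging some null variant; the distortion test exists to judge whether
removal matters. Second, a single variant carrying a dominant share of the
total IVW weight can *mask* its own outlyingness by dragging every
leave-one-out slope toward itself — an inherent limitation of
residual-based outlier detection, not an implementation artifact.

## The simulator and what it does (not) emulate

`simulate_gwas_pair()` generates effects directly on the summary scale.
Defaults were fixed to the regime the package is validated under: 50
instruments jointly explaining 2% of a unit-variance continuous exposure
(per-variant shares exponential — real per-locus contributions are
strongly skewed, and exactly equal shares would make instrument strength
nearly collinear with outcome precision, a degenerate geometry for Egger
regression), exposure GWAS $n = 339{,}224$, binary outcome with 6,406
cases / 902,088 controls, allele frequencies uniform on (0.05, 0.95), 10%
palindromic allele pairs. Outcome standard errors use the effective sample
size $n_\mathrm{eff} = 4/(1/n_\mathrm{case} + 1/n_\mathrm{control})$, so
extreme case/control imbalance propagates correctly into precision.
Instruments are oriented to the exposure-increasing allele
($\gamma_j > 0$), the convention of published instrument tables; without
this, "directional" pleiotropy would have no direction after MR-Egger's
sign reorientation. Directional-pleiotropy simulations set the mean direct
effect to twice the median outcome standard error with spread half the
mean — large enough to matter, small enough not to dominate. Exposure and
outcome noise are drawn from separate RNG streams derived from the single
seed, honoring two-sample independence.

`simulate_multi_exposure()` adds exposure-on-exposure path coefficients:
variants of exposure $q$ acquire downstream effects
$\Gamma = (I-B)^{-1}G$ on later exposures, so an outcome generated with
effect only through a mediator exhibits the signature this package's
multivariable MR is designed to detect — a clearly positive univariable
estimate for the source exposure whose conditional estimate collapses to
zero.

What the simulator does *not* emulate: LD between instruments (variants
are independent by construction, i.e. post-clumping), individual-level
genotypes, winner's-curse selection of instruments, sample overlap between
the exposure and outcome GWAS, and allele-frequency differences between
the two samples. Passing calibration on simulated data therefore validates
the estimators and plumbing under the stated generative model, not
robustness to those real-data complications.

## Numerical and reporting conventions

* Bootstrap standard errors (median, mode) default to 1,000 replicates and
  require an explicit seed, recorded in the estimate; the mode's bandwidth
  is `bandwidth_factor` (default 1) times the scaled median absolute
  deviation of the ratios (falling back to the standard deviation when the
  MAD collapses), with the argmax located on a 2,001-point grid spanning
  the ratios ± 3 bandwidths.
* Leave-one-out flags variants whose omission moves the estimate by more
  than `se_multiple` (default 1) full-data standard errors.
* The Bonferroni display rule reports the *exact* threshold together with
  the shortest decimal within 5% relative error — the rounding style of
  study reports, which prints 0.05/34 as 0.0015 and 0.05/8 as 0.006.
* `detectable_or()` uses the normal-approximation power formula with
  $se_\mathrm{IVW} \approx 1/\sqrt{n_\mathrm{eff}\, r^2}$, the same
  effective-sample-size convention as the simulator — so the formula and
  the generator agree, and the Monte-Carlo validation in the test suite
  closes. Detectable effects are reported per SD of the exposure.
* Results serialize to TSV (15 significant digits) or JSON (full
  precision); numeric fields survive a read-back round trip to at least 12
  significant digits.

## Validation protocol

The test suite validates each estimator against an independent route
(brute-force weighted least squares via `lm`, grid-search quantile and
density oracles, rule-replay of the clumping and harmonization logic) and
runs a statistical battery at these problem sizes, chosen as the package's
standing validation protocol: 50 oracle-equivalence fixtures (agreement to
10 significant digits); parameter recovery at $\theta \in \{0, 0.1, 0.3\}$
with 500 replicates each (mean within 3 Monte-Carlo standard errors, 95%
CI coverage required to land in [0.93, 0.97]); 2,000 null replicates for
type-I error (99% binomial band around 0.05) and Cochran-Q uniformity
(Kolmogorov–Smirnov at $\alpha = 0.01$); 500 directional-pleiotropy
replicates for Egger-intercept power (> 50% required) and IVW bias; ten
seeded MR-PRESSO batteries (clean and single-outlier); and one mediation
design for multivariable attenuation. `scripts/acceptance.R` recomputes
all of these from scratch for any seed.

## Known limitations

Beyond the simulator's scope (above): no MR-RAPS/debiased IVW, no Steiger
directionality filtering, no nonlinear or threshold exposure–outcome
models, no correlated-instrument (generalized IVW) support — the LD source
exists to *prune* correlation, not to model it — and no LD computation
from genotype panels (supply a pairwise table or matrix instead).
Conditional instrument-strength inference uses the plain $\chi^2_{k-m}$
reference rather than a heteroskedasticity-robust variant. The
liability-scale conversion degrades for large per-variant effects
(log OR per allele $\gtrsim 1$), which are rare in the intended complex-
trait setting.
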