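---
title: "Drug-target Mendelian randomisation with dtmr: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target Mendelian randomisation with dtmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtmr)
```

## The design

Two-sample Mendelian randomisation treats genetic variants as instrumental
variables: a variant that alters an exposure, and is inherited independently
of confounders, lets us estimate the causal effect of the exposure on an
outcome from two separate GWAS — one for the exposure, one for the outcome —
without individual-level data. The *drug-target* (cis) flavour restricts the
instruments to variants in or near the gene encoding a drug's protein
target. Their effect on a downstream biomarker (here the canonical example
is C-reactive protein, CRP, as a readout of anti-inflammatory drug action)
stands in for pharmacological modulation of the target, so the MR estimate
is interpreted as the effect of taking the drug — reported as an odds ratio
per unit *decrease* in the log biomarker, `OR = exp(-theta)`, where `theta`
is the estimated log-odds of the outcome per unit log-biomarker increase.

The package implements this design end to end: instrument selection,
harmonisation, a battery of estimators with different validity assumptions,
pleiotropy and influence diagnostics, and a synthetic-data generator so the
whole machine can be validated with a known truth.

## Instrument selection

Selection mirrors the standard cis-proxy flow, in order:

1. **Region extraction.** Variants whose position falls inside any of the
   target's gene, promoter or enhancer intervals (the catalog is an input;
   the package never looks regions up). The count of these variants is `n`.
2. **Bonferroni thresholding.** Keep variants with exposure p-value strictly
   below `alpha / n` (default `alpha = 0.05`). Counting `n` *before*
   significance filtering makes the threshold a property of the region, not
   of the data.
3. **Greedy LD clumping.** Repeatedly take the smallest-p unclaimed variant
   as an index and discard unclaimed variants with `r² >= r2_max` (default
   0.1) to the index *and* within `window_bp` (default 1 Mb) of it. The two
   conditions are combined with AND — a variant is only discarded if both
   linked and near — matching standard clumping semantics. Ties in p are
   broken by rsid so output is deterministic. Pairs absent from the LD
   matrix default to `r² = 0` with a warning ("lenient" mode; `strict`
   errors instead), because reference panels never cover every variant.
4. **Palindrome exclusion.** A/T and C/G variants are removed
   unconditionally (default). Because exclusion is unconditional, the
   harmonisation step never needs allele-frequency-based strand inference.

All coordinates are 1-based inclusive in memory; BED input is converted on
read so the clumping-window arithmetic has a single convention. The genome
build is metadata only — the package never lifts coordinates between builds.

## Harmonisation and orientation

Exposure and outcome records are joined on rsid. Matching allele pairs are
copied; swapped pairs negate the outcome effect; incompatible pairs are
dropped with a logged reason, as are variants missing from the outcome GWAS
(the drop log travels with the harmonised table). Estimation then happens on
the biomarker-increasing orientation: instruments with negative exposure
effects have both effects jointly negated, which leaves every ratio-based
estimator unchanged but fixes the sign convention that MR-Egger (which is
not invariant to per-variant flips) and the reporting transform rely on.

## Estimators

Let `beta_Xj ± se_Xj` and `beta_Yj ± se_Yj` be the harmonised effects and
`w_j = 1/se_Yj^2`.

- **Wald ratio** (k = 1): `theta = beta_Y/beta_X`, first-order SE
  `se_Y/|beta_X|`.
- **IVW, multiplicative random effects** (k >= 2):
  `theta = sum(w beta_X beta_Y) / sum(w beta_X^2)` — a weighted regression
  through the origin. The fixed-effect SE `(sum w beta_X^2)^(-1/2)` is
  inflated by `max(1, sqrt(Q/(k-1)))`, with Q Cochran's statistic at the
  fixed-effect slope. The floor at 1 means heterogeneity can only widen the
  interval, never narrow it below the fixed-effect one — the prevailing
  two-sample-MR convention.
- **Weighted median** (k >= 3): the 50% weighted percentile (midpoint
  interpolation over sorted ratios) of the per-variant ratios under
  inverse-variance weights with first-order ratio SEs (a second-order
  option that includes the exposure SE is available behind a flag).
  Consistent when valid instruments carry at least half the weight. The SE
  is a parametric bootstrap: effects are resampled from normals at their
  reported SEs (default 1000 replicates, explicit seed required).
- **Weighted mode** (k >= 3): the argmax of a Gaussian kernel density over
  the ratios with inverse-variance weights. The bandwidth is
  `phi * 0.9 * mad(ratios) * k^(-1/5)` — a robust Silverman-type rule; the
  sample SD substitutes when the MAD degenerates to zero, and identical
  ratios return the common value directly. The mode is located on a
  512-point grid spanning the ratio range plus three bandwidths; `phi`
  defaults to 1. The bootstrap SE uses the (scaled) MAD of the bootstrap
  modes, which is robust to the multimodality bootstrap mode distributions
  often show.
- **MR-Egger** (k >= 3): weighted least squares of `beta_Y` on `beta_X`
  with an intercept, computed from the weighted normal equations. Both SEs
  use the unit-dispersion `(X'WX)^(-1)` form inflated by
  `max(1, residual scale)` — the same floored-inflation convention as IVW,
  and numerically safe when the fit is exact (where a residual-scale
  division would be 0/0). The intercept estimates the average directional
  pleiotropic effect per variant under the InSIDE assumption, and its
  two-sided normal p-value is the pleiotropy test.
- **MR-RAPS** (k >= 3): profile-score estimation in `(theta, tau2)` with
  standardised residuals
  `t_j = (beta_Yj - theta beta_Xj)/sqrt(se_Yj^2 + theta^2 se_Xj^2 + tau2)`.
  The theta score is `sum(psi(t_j) dt_j/dtheta) = 0` with `psi` either the
  identity (l2) or the Huber function (default, tuning constant 1.345); the
  overdispersion moment is `sum(psi(t_j) t_j - delta) = 0` with
  `delta = E[psi(Z) Z]` for standard normal Z (`2*pnorm(c)-1` for Huber),
  and `tau2` clamped at zero when the moment is negative there. The solve
  is nested one-dimensional root finding and is deterministic; a seed is
  consulted only if deterministic bracketing fails and randomised restarts
  are needed. The SE is the model-based expected-information variance of
  the profile score, `E[psi^2] / (E[psi']^2 sum(d_j^2))` with
  `d_j = dt_j/dtheta`: in the l2 limit with negligible exposure error this
  is exactly the fixed-effect IVW variance, and at the instrument counts
  typical of cis analyses it holds nominal coverage where the empirical
  (HC0-style) sandwich is biased low and undercovers.
- **MR-PRESSO** (k >= 4): the observed statistic is the weighted residual
  sum of squares around leave-one-out IVW expectations; its null is
  simulated by drawing effects from normals centred at the leave-one-out
  fit (add-one-corrected Monte-Carlo p, default 1000 simulations).
  Per-variant outlier p-values are each variant's rank within its own
  simulated residual distribution, Bonferroni-adjusted; because the add-one
  empirical p has a floor of `1/(n_sim+1)`, the adjusted p can only fall
  below 0.05 when `n_sim` exceeds roughly `20 k` — another reason the 1000
  default should not be reduced for outlier detection. The corrected
  estimate is IVW on the unflagged set, and the distortion test compares
  the observed estimate shift against shifts from removing random subsets
  of the same size drawn from the *non-flagged* instruments (removing a
  random valid set is the reference against which removing the flagged set
  is judged; drawing from all instruments would let the null reproduce the
  observed distortion and destroy the test's power).

All CIs use the normal 1.96 multiplier; bootstrap CIs are normal intervals
on the bootstrap SE. Methods whose instrument-count precondition fails are
reported as explicitly not-applicable, never silently dropped — a
single-instrument target yields a Wald ratio plus five markers.

## Diagnostics

Cochran's Q (at the fixed-effect IVW slope, `k - 1` degrees of freedom),
leave-one-out IVW estimates, and a Cook's-distance screen computed from the
weighted through-origin regression (consistent with the IVW model; an
intercept model is available via `model = "intercept"`). The Cook's
threshold defaults to `4/k` — the method prescribes no cut-off, and `4/k`
is the common default — and the full estimator battery is re-run on the
surviving instruments. Scatter (effect vs effect, with fitted lines per
method) and funnel (ratio vs precision) tables are exported; rendering is
left to the user, the tables are the contract.

## The synthetic-data generator

`simulate_two_sample()` draws true exposure effects as half-normal
magnitudes `|N(0, beta_x_scale^2)|` — effects expressed on the
biomarker-increasing allele, as cis instruments conventionally are; with
signed effects, re-orientation would sign-flip the direct effects and
collapse a directional pleiotropy regime into a balanced one. Observed
effects add Gaussian noise at the stated SEs, and outcome effects are
`theta_true * gamma_j + alpha_j + noise` with `alpha_j` per regime:

- `none`: zero;
- `balanced`: zero-mean normal of SD `pleiotropy_mag` on all variants;
- `directional`: mean `pleiotropy_mag` on a `pleiotropy_frac` minority
  (default 0.4 — a biased minority, the scenario the weighted median is
  designed for);
- `inside_violating`: proportional to the true exposure effect, breaking
  the InSIDE assumption that MR-Egger needs.

Defaults echo a cis-instrument biomarker analysis at the scale of a
several-hundred-thousand-sample biomarker GWAS paired with a binary-outcome
GWAS of order ten thousand cases: `k = 18` instruments, exposure effects of
a few percent of a log-unit (`beta_x_scale = 0.05`) with small exposure SEs
(`se_x = 0.004`), outcome SEs of 0.04 on the log-odds scale, and a causal
slope `theta_true = 0.58` (OR 0.56 per unit biomarker decrease). P-values
are computed from the observed z-statistics (floored at 1e-300 to respect
the `p > 0` invariant; biomarker z-scores at this instrument strength can
otherwise underflow). Outcome effects are generated directly on the
log-odds scale — no individual-level binary model — which is sufficient for
summary-statistic methods and fast; what the generator consequently does
*not* emulate includes case-control ascertainment and non-collapsibility
effects, allele-frequency-dependent power, genuine LD-induced correlation
between instrument effect estimates (the LD matrix exists for clumping, but
effects are drawn independently), and sample overlap between the two GWAS.
Passing tests therefore demonstrate correctness of the estimators under
their own assumptions, not robustness to every pathology of real data.

`simulate_region_scenario()` plants significant variants inside a
single-target region (optionally in constant-`r²` LD blocks, optionally
palindromic) together with non-significant in-region decoys (which enlarge
the Bonferroni denominator) and out-of-region variants. Its truth record
states the exact counts and variant set the selection flow must deliver —
per block only the smallest-p member survives clumping when the block `r²`
reaches the threshold, and palindromic survivors are removed last —
computed by construction, not by re-running the package's own clumping.
Palindromic status is planted on variants that survive clumping so the
final count is deterministic.

Every randomised operation takes an explicit seed (`withr::with_seed`, no
global RNG state), so identical configurations are bit-identical.

## Numerical and design choices

- **Empirical p-values** use the add-one correction
  `(1 + #{T* >= T_obs})/(n_sim + 1)`, so a Monte-Carlo p is never zero.
- **Validation is total**: malformed summary-statistic rows raise typed,
  row-numbered errors; LD matrices must be square, symmetric (tolerance
  1e-8), unit-diagonal and in `[0, 1]`; duplicate rsids are rejected.
- **Degenerate inputs**: zero exposure effects are dropped at orientation
  (undefined ratio, with a warning); identical ratios short-circuit the
  mode search; an exact Egger fit yields zero-width SE inflation rather
  than 0/0; MR-PRESSO flagging all instruments is a degenerate-correction
  error rather than a silent empty estimate.
- **Per-pair error isolation**: in `run_analysis()` a failing target ×
  outcome pair records its error and the rest of the batch continues; the
  forest table shows the failure inline.
- **Determinism**: reports are byte-identical across reruns of the same
  configuration; the provenance block carries a canonical-JSON MD5 hash of
  the configuration and the seed.
- **Bootstrap defaults**: 1000 replicates, seed mandatory; `n_boot = 0`
  returns the point estimate only (used by the simulation studies where
  only point estimates are compared).

## Validation studies shipped with the package

The test suite and `scripts/acceptance.R` run the following studies, sized
to be decisive yet quick on a single CPU:

- **Oracle equivalence**: IVW, Egger and Q against independently coded
  `lm()`-based weighted-least-squares oracles on 200 random instances
  (agreement to 1e-10), and greedy clumping against an exhaustive
  step-by-step simulation of the rule on random instances of up to 8
  variants.
- **Null calibration**: 2000 replicates at `theta = 0`, `k = 18`: IVW
  rejection and Egger-intercept rejection at the 5% level, and 95% CI
  coverage.
- **Robustness ordering**: 500 paired replicates with large directional
  pleiotropy (mean direct effect 0.15, several times the per-variant
  genetic outcome effect, on 40% of instruments): the weighted median's
  absolute error beats IVW's in the large majority of replicates.
- **MR-PRESSO power**: a single injected 10-sigma outcome outlier among 20
  instruments is flagged in essentially every seeded run; the distortion
  test rejects when the outlier dominates the estimate and is not
  applicable when nothing is flagged.
- **Selection fixture**: the planted region scenario (10 significant, one
  `r² = 0.9` pair, one palindrome, 30 decoys) reproduces its truth record
  exactly: counts 40 / 10 / 9 / 8 and the exact surviving variant set.

## Known limitations

- No proxy-variant substitution for instruments absent from the outcome
  GWAS (they are dropped with a logged count), no liftover, no
  reference-panel LD computation from genotypes, no multivariable MR, no
  Steiger filtering.
- The weighted median/mode weights use first-order ratio SEs by default;
  with very weak instruments the second-order option is more appropriate.
- MR-PRESSO is simulation-based only; no asymptotic approximation is
  offered, so `n_sim` governs both the granularity of its p-values and the
  attainable significance after Bonferroni adjustment.
- The RA-style mixed-ancestry outcome question is out of scope: outcome
  summary statistics are treated as opaque inputs.
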