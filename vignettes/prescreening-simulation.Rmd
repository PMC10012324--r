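---
title: "Methods: the two-stage amyloid pre-screening simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the two-stage amyloid pre-screening simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petscreen)
```

# The problem

Secondary prevention trials of Alzheimer's disease recruit cognitively
unimpaired (CU) elderly participants but require confirmed amyloid
pathology — in practice a positive amyloid PET scan — before inclusion. With
a PET+ prevalence near 29% in enriched CU cohorts, roughly seven of every
ten screening scans are negative and wasted. `petscreen` quantifies how much
a cheap plasma first stage (Aβ42/Aβ40 ratio, *APOE* ε4 status, age) can
reduce the number of scans and the total recruitment cost, and with what
uncertainty.

# The risk model

PET status $y_i \in \{0,1\}$ is modelled by logistic regression,

$$\operatorname{logit} P(y_i = 1) =
  \beta_0 + \beta_1 z(-x_i^{A\beta}) + \beta_2 \, a_i + \beta_3 z(t_i),$$

where $x^{A\beta}$ is the plasma Aβ42/Aβ40 ratio, $a$ the ε4 carrier flag,
and $t$ age.

Preprocessing conventions, all in `preprocess()`:

* **Negation.** The plasma ratio *falls* with pathology, so it is multiplied
  by −1 before use; the plasma coefficient is then positive.
* **Per-SD scale.** Continuous predictors are z-scored, so $e^{\beta_1}$ and
  $e^{\beta_3}$ are odds ratios per SD. On the raw ratio scale (SD ≈ 0.01) a
  plasma OR near 6 would be impossible, so per-SD is the only reading
  consistent with the effect sizes this model reproduces; a raw-unit
  interpretation is not offered.
* **Carrier collapse.** ε4 homozygotes are rare at this cohort size, so the
  allele count is collapsed to "at least one ε4 allele".

`fit_logistic()` is a self-contained IRLS (Newton) maximizer with
step-halving: convergence when the score norm falls below $10^{-8}$, at most
100 iterations. Complete separation — a real hazard in small bootstrap
resamples — is detected by non-convergence or coefficients beyond ±15 on the
standardized scale; the fit is then repeated with a ridge penalty of
$10^{-8}$ on non-intercept coefficients and flagged. The ridge does not
meaningfully shrink estimable fits; it only renders the separated optimum
finite so downstream ranking statistics stay defined. The test suite
cross-checks the fitter against `stats::glm` and against the exact
contingency-table odds ratio on 2×2 data.

`auc()` uses the Mann–Whitney midrank form (ties get half credit), verified
against brute-force pairwise enumeration on small inputs.

# Resampling inference

* **Bootstrap** (`bootstrap_statistic()`): participant-level resampling with
  replacement, B = 1000 by default. The model is refit inside each resample
  and, in relative mode, percentile cutoffs are recomputed from the
  resample — the resample is treated as the screened population.
  Percentile (2.5%, 97.5%) intervals; two-sided p-values use the
  sign-fraction convention $2\min\{P(\hat\theta \le \theta_0),
  P(\hat\theta \ge \theta_0)\}$ floored at $1/B$, since a resampling p-value
  of exactly zero is not meaningful. BCa corrections are deliberately not
  used: with refit-per-resample statistics the percentile interval is the
  transparent choice and matched the reported interval widths in this
  design. Resamples with a single outcome class are discarded and redrawn
  (with a $10B$ budget), so every retained replicate is fittable.
* **Cross-validation** (`cross_validate()`): folds stratified by PET status
  (stratification keeps every training fold two-class at n = 180),
  standardization recomputed on each training fold — no leakage — and AUC
  pooled over held-out predictions. The CI comes from repeating the fold
  assignment; `k = n` gives exact leave-one-out, which the suite checks
  against direct enumeration.

# The screening and cost model

For threshold $q$ (relative) the top $\lceil (1-q) n \rceil$ participants by
predicted risk are invited, boundary ties broken by stable input order; for
cutoff $c$ (absolute), all with risk ≥ c. Yield is the PET+ fraction among
invited. Recruiting $N$ PET+ participants then needs
$n_{PET} = \lceil N / \mathrm{PPV} \rceil$ scans and
$n_{plasma} = \lceil n_{PET} / f \rceil$ plasma tests ($f$ = invited
fraction); ceilings because partial tests do not exist. With $f = 1$ the
first stage is not run at all and $n_{plasma} = 0$.

Costs are expressed in plasma-test units: $C = n_{plasma} + r\,n_{PET}$ with
$r$ the PET-to-plasma cost ratio (grid 4, 8, 16). Only the ratio matters —
rescaling both unit costs cancels in
$\Delta = 100\,(C - C_0)/C_0$, where the baseline $C_0 = r\,n_{PET}(q{=}0)$
carries no plasma cost. Useful identities pinned by the tests: pre-screening
that saves no scans costs exactly $+100/r$ percent; as $r \to \infty$,
$\Delta$ tends to the pure scan-reduction percentage; $\Delta < 0$ iff the
plasma bill is below the value of the scans saved.

Two reporting conventions coexist deliberately. The *plug-in* columns use
full-cohort counts. The *bootstrap-mean* columns average per-resample counts;
because $E[1/\mathrm{PPV}] \ge 1/E[\mathrm{PPV}]$ (Jensen), the
bootstrap-mean scan count always weakly exceeds the count implied by the
bootstrap-mean yield, and this is the headline convention in the literature
this design follows. Note the full-cohort plug-in count can exceed the
bootstrap mean at high thresholds, because refitting inside each resample
makes the resample's own yield optimistic; the suite asserts the Jensen
direction in its exact form and the plug-in comparison only at threshold 0,
where no refitting enters. Δcost bootstrap draws are *paired*: both arms of
each difference come from the same resample, which is what produces the
narrow intervals this design reports.

# The synthetic cohort generator

No participant-level data are distributable, so `generate_cohort()` emulates
the study population; every distributional default is a study condition, not
a tuning knob:

| quantity | default | source/constraint |
|---|---|---|
| n | 180 | cohort size |
| PET+ prevalence | 52/180 | cohort PET table |
| age | mean 73.01, SD 5.29, truncated to [60, 90] | cohort demographics |
| ε4 carrier marginal | 61/180; homozygotes 10/61 of carriers | allele table |
| plasma ratio marginal | 0.13 (0.01) | cohort biomarker table |
| SUVR components | PET−: N(0.65, 0.04²); PET+: N(0.93, 0.10²) | see below |
| SUVR cutoff | 0.742 | published mixture-model threshold |
| sex, education | 61.7% female; 11.90 (3.32), ≥ 0 | realism only, never modelled |

Generation order: PET status first (Bernoulli), then APOE, plasma and SUVR
from class-conditional distributions. Age is independent of status by
default (`age_beta = 0`) because the fitted age effect in this design is
null (OR ≈ 1.1, p ≈ 0.6); `age_beta` is exposed for sensitivity work and
preserves the marginal prevalence by re-solving the intercept. A
group-conditional prevalence option (`group_prevalence = c(CN = 0.20,
SCD = 0.40)`) reproduces the subgroup rates but is off by default, keeping
the default generator exchangeable across diagnosis groups.

**Age truncation correction.** `age_mean` is the mean of the *observed*
(truncated) distribution — that is what a cohort table reports. The
generator solves for the pre-truncation location by inverting the
truncated-normal mean formula (location ≈ 72.91 for a target of 73.01), then
samples by inverse-CDF. `age_sd` remains the pre-truncation scale; the
realized SD is ≈ 5.1, slightly below 5.29, which we accept rather than
jointly inverting both moments. This convention was chosen because the
calibration target is the printed cohort mean.

**SUVR components.** Only the SUVR marginal (0.73, SD 0.15) and the cutoff
0.742 are constrained. The defaults N(0.65, 0.04²) / N(0.93, 0.10²) at
prevalence 52/180 give marginal mean 0.731, SD 0.142, and 98.4% agreement
between the latent class and thresholding at 0.742. Because SUVR is
generated as a noisy measurement of the latent class, a ~1.6% discordant
fraction between `pet_status` and thresholded SUVR is *expected*;
`validate_cohort()` therefore warns (rather than errors) on discordance
above 5%, and derives status from SUVR only when the status column is
absent.

**Mixture cutoff convention.** `derive_suvr_cutoff()` fits a two-component
unequal-variance Gaussian mixture by EM (via mclust) and returns the point
between the component means where posterior membership is 0.5 — the crossing
of the weighted densities, solved analytically from the fitted parameters.
Alternatives (e.g. negative-component mean + 2 SD) exist in the field; the
posterior-0.5 convention is symmetric in the components and is the one
implemented. On the default generator it lands near 0.75, close to but not
identical with the published 0.742, which was derived from a different
sample.

# Closed-form effect calibration

The class-conditional plasma means and carrier rates are *not* reported by
cohort tables; only marginals and fitted effects are. `calibrate_effects()`
recovers them exactly rather than by search, using the fact that the
generator's structure makes the true risk model logistic:

* APOE and plasma are conditionally independent given PET status, so the
  APOE coefficient is the log cross-ratio of the carrier rates. Fixing the
  cross-ratio at the target OR (3.67) and the marginal carrier rate at
  61/180 gives one equation in one unknown: carrier rates 0.252 / 0.553.
* With equal within-class SDs $s$, the plasma coefficient is
  $d/s^2$ per raw unit ($d$ = class separation), i.e.
  $\beta_{SD} = d \sigma_m / s^2$ per marginal SD
  $\sigma_m$. Fixing $\beta_{SD} = \log 5.98$, the marginal SD at
  $\sigma_m^2 = s^2 + p(1-p) d^2 = 0.01^2$ and the marginal mean at 0.13
  yields a quadratic with the unique admissible solution
  $d = 0.0123$, $s = 0.0083$, class means 0.1336 / 0.1212.

These two constraints plus the marginals *fully determine* the model AUC —
there is no independent AUC dial. The implied population AUC is 0.873
(computed exactly by mixing the binormal plasma part over APOE pairs; the
binormal special case $\Phi(d/\sqrt2)$ is pinned in the tests), and the mean
*in-sample* fitted AUC at n = 180 is 0.877 (optimism of ~0.005 from fitting
three coefficients on 180 observations), inside the 0.87 ± 0.01 target band.
`calibrate_effects()` therefore treats the AUC target as a consistency
requirement: it verifies it by Monte-Carlo simulation at the configured
cohort size and fails with diagnostics when the odds-ratio targets and the
AUC target are jointly unreachable (e.g. a demanded AUC of 0.99).

# What the generator does and does not emulate

Passing tests on synthetic cohorts demonstrate that the *pipeline* —
preprocessing, fitting, resampling, threshold and cost arithmetic — behaves
correctly under the study conditions, and that the generator reproduces the
marginal structure and effect sizes it was calibrated to. They do not
validate the biology: the generator draws plasma and SUVR from clean
Gaussians with a common within-class SD, has no assay noise or batch
effects, no plasma–age or plasma–APOE correlation within PET class, no
longitudinal drift, and no screen failures for non-biomarker reasons. Real
yields and savings will differ to the extent real data violate those
simplifications.

# Problem sizes and numerical choices

Simulation sizes used by the suite and the acceptance script are chosen to
put Monte-Carlo error well inside the decision tolerances: marginal-moment
checks at n = 10⁵ (binomial/truncated-normal SEs ≲ 0.003), odds-ratio
recovery at n = 2×10⁵ (log-OR SE ≈ 1%, against a 5% tolerance), and the
mean-AUC check over 2000 cohorts of n = 180 in the acceptance script (SE
≈ 0.0006 against a ±0.01 band; the test suite uses 200 cohorts under a fixed
seed). Bootstrap defaults to B = 1000; unit tests use B = 200–400, which is
ample for the directional and bracketing properties they assert.

Other fixed choices: IRLS tolerance $10^{-8}$/100 iterations; ridge guard
$10^{-8}$; AUC tie handling by midranks; percentile CIs; p-value floor
$1/B$; ceiling rounding of all test counts; stable-order tie-breaks in
relative invitations (seed-independent); EM for the SUVR mixture capped at
1000 iterations, tolerance $10^{-8}$, with degenerate inputs (single
component, identical values, < 50 observations) raising errors rather than
returning a cutoff.

# Known limitations

* The per-SD odds-ratio convention is an interpretation; raw-unit ORs are
  not implemented because they are dimensionally inconsistent with the
  targeted effect sizes.
* The generator's Gaussian-mixture SUVR model makes the mixture-cutoff
  derivation easy; real SUVR distributions are skewed and the posterior-0.5
  point is assay- and sample-dependent.
* Bootstrap-mean headline counts are reported alongside plug-in counts; at
  high thresholds with small invited fractions the two can differ by refit
  optimism (see the resampling section), and neither is uniformly superior.
* Cost modelling is strictly relative (ratio r); fixed site costs, staged
  recruitment and non-monetary burdens are out of scope.
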