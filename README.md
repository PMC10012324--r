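# petscreen

Simulation tools for **plasma-biomarker pre-screening** in secondary
prevention trials of Alzheimer's disease.

Trials that require amyloid PET positivity for inclusion waste most of their
screening budget on negative scans: in cognitively unimpaired (CU)
populations only ~25–30% of candidates are PET-positive. A cheap first-stage
plasma panel — the Aβ42/Aβ40 ratio, *APOE* ε4 carrier status and age — can
triage who is sent on to the expensive confirmatory PET scan. `petscreen`
implements that two-stage design end to end:

1. **Risk model.** A logistic regression for PET status,

   logit P(PET+) = β₀ + β₁·z(−Aβ42/40) + β₂·ε4carrier + β₃·z(age),

   with the plasma ratio negated (higher = more pathology) and continuous
   predictors z-scored, so exp(β) are per-SD odds ratios. Fitting is by
   iteratively reweighted least squares with a ridge guard against complete
   separation; performance is estimated by participant-level bootstrap
   (percentile CIs, 1000 resamples) and stratified 5-fold cross-validation.
2. **Threshold sweep.** Invitation rules in two modes — *relative* risk
   (invite the top 1−q of the ranked population) and *absolute* risk (invite
   everyone with predicted probability ≥ c) — swept over a grid of
   thresholds. For each threshold: the PET+ yield (PPV) among invited, and
   the test counts needed to recruit `n_target` PET-positive participants,
   `n_PET = ⌈n_target/PPV⌉`, `n_plasma = ⌈n_PET/f⌉` (f = invited fraction).
3. **Cost model.** Total recruitment cost `n_plasma + r·n_PET` in
   plasma-test units, with PET-to-plasma cost ratios r ∈ {4, 8, 16}, and the
   percentage change Δcost versus scanning everyone, with paired bootstrap
   CIs and p-values.
4. **Synthetic cohort generator.** The reference cohort is not publicly
   deposited, so the package ships a generator emulating its structure
   (n = 180 CU participants, 28.9% PET+, age 73.0 (5.3) truncated at 60,
   61/180 ε4 carriers, plasma ratio 0.13 (0.01), SUVR ≈ 0.73 with positivity
   cutoff 0.742). Class-conditional effect sizes are calibrated in closed
   form so the fitted model reproduces per-SD plasma OR ≈ 5.98, APOE
   OR ≈ 3.67 and AUC ≈ 0.87 at n = 180 — see `calibrate_effects()` and the
   vignette for the derivation. A mixture-model SUVR cutoff derivation
   (`derive_suvr_cutoff()`) is included.

## Worked example

```r
library(petscreen)

cohort <- generate_cohort(generator_config(seed = 42))
model  <- fit_risk_model(cohort)
model
#> <risk_model> variant 'full' fitted on n = 180 (62 PET+)
#>   OR plasma Abeta42/40 (negated, per SD)    7.052  (beta = +1.9532)
#>   OR APOE e4 carrier                        4.309  (beta = +1.4606)
#>   OR age (per SD)                           1.447  (beta = +0.3697)

cross_validate(cohort, k = 5, repeats = 20, seed = 42)
#> <performance_estimate> cv AUC = 0.868, 95% CI (0.859, 0.874)

sweep <- screen_sweep(cohort, mode = "relative",
                      grid = seq(0, 0.75, 0.25), B = 1000, seed = 42)
sweep[, c("threshold", "ppv_boot", "ppv_lo", "ppv_hi",
          "n_pet_boot", "n_plasma_boot")]
#>   threshold ppv_boot ppv_lo ppv_hi n_pet_boot n_plasma_boot
#> 1      0.00    0.344  0.272  0.411       1470             0
#> 2      0.25    0.458  0.363  0.548       1103          1471
#> 3      0.50    0.603  0.489  0.711        837          1674
#> 4      0.75    0.782  0.622  0.911        646          2585

costs <- cost_sweep(sweep, ratios = c(4, 8, 16))
subset(costs, threshold == 0.5)[, c("ratio", "delta_boot", "delta_lo",
                                    "delta_hi", "p_value")]
#>    ratio delta_boot delta_lo delta_hi p_value
#> 3      4      -14.4    -22.2    -5.13   0.006
#> 7      8      -28.7    -35.2   -20.94   0.001
#> 11    16      -35.8    -41.7   -28.85   0.001
```

Reading this run: with no pre-screening (threshold 0) every recruit is
scanned and 34.4% of scans are positive, so ~1470 scans recruit 500 PET+
participants. Inviting only the top half by predicted risk raises the yield
to 60% — 837 scans plus 1674 plasma tests — and cuts total recruitment cost
by 29% (CI −35 to −21) when a PET scan costs 8× a plasma test. This cohort
(seed 42) drew a somewhat stronger effect than average; across repeated
cohorts the fitted ORs centre on 5.98 / 3.67 and the AUC on ~0.87.

`run_pipeline()` executes the whole chain (generate → fit → sweep both modes
→ costs → figures) and writes `cohort.csv`, `model.json`,
`screening_<mode>.csv`, `costs.csv` and `summary.md` into a run directory,
byte-reproducibly for a given seed.

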