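#' Configuration for the synthetic cohort generator
#'
#' Builds the full parameter set for [generate_cohort()]. The defaults emulate
#' a cognitively unimpaired memory-clinic cohort of n = 180 with 28.9% amyloid
#' PET positivity: age 73.0 (5.3) years truncated at 60, an APOE e4 carrier
#' fraction of 61/180, an overall plasma A-beta 42/40 ratio of 0.13 (0.01) and
#' PET SUVR of about 0.73 (0.14) with positivity cutoff 0.742.
#'
#' The class-conditional plasma and APOE parameters default to the closed-form
#' calibration of [calibrate_effects()] at odds-ratio targets 5.98 (plasma,
#' per SD) and 3.67 (APOE carrier), which reproduces a three-predictor model
#' AUC of about 0.87 at n = 180 (see the package vignette for the derivation).
#'
#' `age_mean` is the target mean of the *truncated* (observed) age
#' distribution; the generator solves for the pre-truncation location so that
#' the sampled mean matches it. `age_sd` is the pre-truncation scale.
#'
#' @param n Number of participants.
#' @param prevalence Marginal probability of PET positivity.
#' @param age_mean,age_sd,age_min,age_max Age distribution: target truncated
#'   mean (years), pre-truncation SD, and truncation bounds.
#' @param carrier_rate_pos,carrier_rate_neg Class-conditional probabilities of
#'   carrying at least one APOE e4 allele given PET-positive / PET-negative
#'   status. `NULL` (default) uses the calibrated values.
#' @param homozygote_fraction Fraction of carriers with two e4 alleles.
#' @param plasma_mean_neg,plasma_mean_pos,plasma_sd Class-conditional Gaussian
#'   parameters of the plasma A-beta 42/40 ratio (common SD). `NULL` uses the
#'   calibrated values.
#' @param suvr_mean_neg,suvr_sd_neg,suvr_mean_pos,suvr_sd_pos Class-conditional
#'   Gaussian parameters of PET SUVR.
#' @param suvr_cutoff SUVR positivity threshold used when deriving PET status
#'   from SUVR (the published mixture-model cutoff).
#' @param age_beta Log-odds of PET positivity per SD of age (0 = age
#'   independent of status, matching the null fitted age effect).
#' @param scd_fraction Fraction of participants with subjective cognitive
#'   decline (the rest are cognitively normal controls).
#' @param group_prevalence Optional named vector `c(CN = , SCD = )` of
#'   group-conditional PET-positive prevalences. When supplied it overrides
#'   `prevalence` within groups (the marginal prevalence then follows from
#'   `scd_fraction`). Default `NULL`: prevalence independent of group.
#' @param female_fraction,education_mean,education_sd Demographic marginals
#'   (education truncated at 0); generated for realism, never modelled.
#' @param seed Optional RNG seed stored in the config; [generate_cohort()] is
#'   deterministic given config + seed.
#'
#' @return An object of class `generator_config` (a named list).
#' @seealso [generate_cohort()], [calibrate_effects()]
#' @examples
#' cfg <- generator_config(n = 500, seed = 1)
#' cohort <- generate_cohort(cfg)
#' mean(cohort$pet_status)
#' @export
generator_config <- function(n = 180,
                             prevalence = 52 / 180,
                             age_mean = 73.01, age_sd = 5.29,
                             age_min = 60, age_max = 90,
                             carrier_rate_pos = NULL, carrier_rate_neg = NULL,
                             homozygote_fraction = 10 / 61,
                             plasma_mean_neg = NULL, plasma_mean_pos = NULL,
                             plasma_sd = NULL,
                             suvr_mean_neg = 0.65, suvr_sd_neg = 0.04,
                             suvr_mean_pos = 0.93, suvr_sd_pos = 0.10,
                             suvr_cutoff = 0.742,
                             age_beta = 0,
                             scd_fraction = 80 / 180,
                             group_prevalence = NULL,
                             female_fraction = 111 / 180,
                             education_mean = 11.90, education_sd = 3.32,
                             seed = NULL) {
  need_cal <- is.null(carrier_rate_pos) || is.null(carrier_rate_neg) ||
    is.null(plasma_mean_neg) || is.null(plasma_mean_pos) || is.null(plasma_sd)
  if (need_cal) {
    cal <- solve_class_conditionals(target_or_plasma = 5.98,
                                    target_or_apoe = 3.67,
                                    prevalence = prevalence,
                                    plasma_marginal_mean = 0.13,
                                    plasma_marginal_sd = 0.01,
                                    carrier_marginal = 61 / 180)
    if (is.null(carrier_rate_pos)) carrier_rate_pos <- cal$carrier_rate_pos
    if (is.null(carrier_rate_neg)) carrier_rate_neg <- cal$carrier_rate_neg
    if (is.null(plasma_mean_neg)) plasma_mean_neg <- cal$plasma_mean_neg
    if (is.null(plasma_mean_pos)) plasma_mean_pos <- cal$plasma_mean_pos
    if (is.null(plasma_sd)) plasma_sd <- cal$plasma_sd
  }

  cfg <- structure(list(
    n = n, prevalence = prevalence,
    age_mean = age_mean, age_sd = age_sd, age_min = age_min, age_max = age_max,
    carrier_rate_pos = carrier_rate_pos, carrier_rate_neg = carrier_rate_neg,
    homozygote_fraction = homozygote_fraction,
    plasma_mean_neg = plasma_mean_neg, plasma_mean_pos = plasma_mean_pos,
    plasma_sd = plasma_sd,
    suvr_mean_neg = suvr_mean_neg, suvr_sd_neg = suvr_sd_neg,
    suvr_mean_pos = suvr_mean_pos, suvr_sd_pos = suvr_sd_pos,
    suvr_cutoff = suvr_cutoff,
    age_beta = age_beta,
    scd_fraction = scd_fraction, group_prevalence = group_prevalence,
    female_fraction = female_fraction,
    education_mean = education_mean, education_sd = education_sd,
    seed = seed
  ), class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (!is.numeric(cfg$n) || length(cfg$n) != 1L || is.na(cfg$n) || cfg$n < 1)
    stop_config("`n` must be a single number >= 1 (got %s)", format(cfg$n))
  probs <- c("prevalence", "carrier_rate_pos", "carrier_rate_neg",
             "homozygote_fraction", "scd_fraction", "female_fraction")
  for (p in probs) {
    if (!is_probability(cfg[[p]]))
      stop_config("`%s` must be a probability in [0, 1]", p)
  }
  if (!is.null(cfg$group_prevalence)) {
    gp <- cfg$group_prevalence
    if (!all(c("CN", "SCD") %in% names(gp)) || !all(vapply(gp, is_probability, TRUE)))
      stop_config("`group_prevalence` must be a named vector c(CN = , SCD = ) of probabilities")
  }
  for (s in c("age_sd", "plasma_sd", "suvr_sd_neg", "suvr_sd_pos", "education_sd")) {
    if (!is.numeric(cfg[[s]]) || cfg[[s]] <= 0)
      stop_config("`%s` must be positive", s)
  }
  if (cfg$age_min >= cfg$age_max)
    stop_config("`age_min` must be below `age_max`")
  if (cfg$plasma_mean_pos > cfg$plasma_mean_neg)
    stop_config("`plasma_mean_pos` must not exceed `plasma_mean_neg` (lower ratio indicates pathology)")
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat(sprintf("  n = %d, PET+ prevalence = %.4f\n", as.integer(x$n), x$prevalence))
  cat(sprintf("  age: mean %.2f (sd %.2f), truncated to [%g, %g]\n",
              x$age_mean, x$age_sd, x$age_min, x$age_max))
  cat(sprintf("  APOE e4 carrier rate: %.3f (PET+) / %.3f (PET-), homozygote fraction %.3f\n",
              x$carrier_rate_pos, x$carrier_rate_neg, x$homozygote_fraction))
  cat(sprintf("  plasma Abeta42/40: %.4f (PET+) / %.4f (PET-), sd %.4f\n",
              x$plasma_mean_pos, x$plasma_mean_neg, x$plasma_sd))
  cat(sprintf("  SUVR: %.2f (%.2f) PET+ / %.2f (%.2f) PET-, cutoff %.3f\n",
              x$suvr_mean_pos, x$suvr_sd_pos, x$suvr_mean_neg, x$suvr_sd_neg,
              x$suvr_cutoff))
  if (!is.null(x$seed)) cat(sprintf("  seed = %s\n", format(x$seed)))
  invisible(x)
}

# Closed-form solve of the class-conditional parameters from marginal
# constraints and conditional odds-ratio targets. Because APOE and plasma are
# conditionally independent given PET status and the plasma components share a
# common SD, the true model P(PET+ | predictors) is exactly logistic (Bayes'
# rule), with per-SD plasma coefficient d/s^2 * sd_marginal and APOE
# coefficient equal to the log cross-ratio of the carrier rates.
solve_class_conditionals <- function(target_or_plasma, target_or_apoe,
                                     prevalence,
                                     plasma_marginal_mean, plasma_marginal_sd,
                                     carrier_marginal) {
  p <- prevalence
  v <- p * (1 - p)

  # carrier rates: cross-ratio = target OR, marginal rate fixed
  R <- target_or_apoe
  if (abs(R - 1) < 1e-12) {
    c0 <- c1 <- carrier_marginal
  } else {
    froot <- function(c0) {
      c1 <- R * c0 / (1 + (R - 1) * c0)
      p * c1 + (1 - p) * c0 - carrier_marginal
    }
    c0 <- stats::uniroot(froot, c(1e-9, 1 - 1e-9), tol = 1e-12)$root
    c1 <- R * c0 / (1 + (R - 1) * c0)
  }

  # plasma separation d and within-class sd s:
  #   beta_perSD = log(OR) = (d / s^2) * sd_marginal
  #   s^2 + p(1-p) d^2 = sd_marginal^2
  bsd <- log(target_or_plasma)
  sm2 <- plasma_marginal_sd^2
  if (abs(bsd) < 1e-12) {
    d <- 0
    s <- plasma_marginal_sd
  } else if (v < 1e-12) {
    # degenerate prevalence: no between-class variance term
    s <- plasma_marginal_sd
    d <- (bsd / plasma_marginal_sd) * s^2
  } else {
    k <- bsd / plasma_marginal_sd # = d / s^2
    d <- (-1 / k + sqrt(1 / k^2 + 4 * v * sm2)) / (2 * v)
    s <- sqrt(d / k)
  }
  m_neg <- plasma_marginal_mean + p * d
  m_pos <- m_neg - d

  list(carrier_rate_pos = c1, carrier_rate_neg = c0,
       plasma_mean_neg = m_neg, plasma_mean_pos = m_pos, plasma_sd = s,
       separation = d)
}

# Population (infinite-n) AUC of the true log-odds score under a config:
# Gaussian plasma part plus the two-point APOE part, age carrying no signal
# when age_beta = 0. Used by calibrate_effects() diagnostics and tested
# against the binormal closed form.
population_auc <- function(cfg) {
  d <- cfg$plasma_mean_neg - cfg$plasma_mean_pos
  s2 <- cfg$plasma_sd^2
  delta <- d^2 / s2            # score mean shift from plasma
  svar <- d^2 / s2             # score variance per class (beta^2 s^2)
  c1 <- cfg$carrier_rate_pos
  c0 <- cfg$carrier_rate_neg
  ba <- if (c1 %in% c(0, 1) || c0 %in% c(0, 1)) 0 else
    log(c1 * (1 - c0) / (c0 * (1 - c1)))
  if (svar == 0 && ba == 0) return(0.5)
  sd2 <- sqrt(2 * svar)
  pr_pair <- function(a1, a0) {
    w <- (if (a1 == 1) c1 else 1 - c1) * (if (a0 == 1) c0 else 1 - c0)
    shift <- delta + ba * (a1 - a0)
    if (sd2 == 0) return(w * ((shift > 0) + 0.5 * (shift == 0)))
    w * stats::pnorm(shift / sd2)
  }
  pr_pair(0, 0) + pr_pair(1, 0) + pr_pair(0, 1) + pr_pair(1, 1)
}

#' Calibrate generator effect sizes to target odds ratios and AUC
#'
#' Solves for the class-conditional plasma means/SD and APOE e4 carrier rates
#' under which (i) the large-sample fitted per-SD plasma odds ratio equals
#' `target_or_plasma`, (ii) the fitted APOE carrier odds ratio equals
#' `target_or_apoe`, while preserving the marginal plasma mean/SD and marginal
#' carrier rate of the base config. Because the generative model is exactly
#' logistic in the predictors, both conditions have a closed-form solution and
#' the model AUC is then fully determined; `target_auc` acts as a consistency
#' requirement which is checked by Monte-Carlo simulation at the cohort size
#' of `base` (mean in-sample AUC of the fitted three-predictor model).
#'
#' @param target_auc Target mean in-sample AUC of the full model at n
#'   cohorts of size `base$n` (0.5 < target_auc < 1).
#' @param target_or_plasma Target per-SD odds ratio for (negated) plasma.
#' @param target_or_apoe Target odds ratio for APOE e4 carriage.
#' @param base Base [generator_config()] supplying marginals and cohort size.
#' @param plasma_marginal_mean,plasma_marginal_sd,carrier_marginal Marginal
#'   constraints preserved by the calibration.
#' @param mc_check If `TRUE` (default) verify the achieved mean AUC by
#'   simulation and fail with diagnostics when it misses `target_auc` by more
#'   than `auc_tol`.
#' @param n_sim Number of simulated cohorts for the AUC check.
#' @param auc_tol Allowed |mean AUC - target_auc|.
#' @param seed Seed for the Monte-Carlo check.
#'
#' @return A `generator_config` with calibrated class-conditional parameters;
#'   attribute `"calibration"` carries the achieved population AUC and, when
#'   checked, the Monte-Carlo mean AUC.
#' @examples
#' cfg <- calibrate_effects(0.87, 5.98, 3.67, base = generator_config(),
#'                          mc_check = FALSE)
#' cfg$plasma_mean_pos < cfg$plasma_mean_neg
#' @export
calibrate_effects <- function(target_auc, target_or_plasma, target_or_apoe,
                              base = generator_config(),
                              plasma_marginal_mean = 0.13,
                              plasma_marginal_sd = 0.01,
                              carrier_marginal = 61 / 180,
                              mc_check = TRUE, n_sim = 200,
                              auc_tol = 0.01, seed = 1L) {
  if (!is.numeric(target_auc) || target_auc <= 0.5 || target_auc >= 1)
    stop_config("`target_auc` must lie in (0.5, 1)")
  if (target_or_plasma < 1 || target_or_apoe < 1)
    stop_config("odds-ratio targets must be >= 1 (effects point towards pathology)")

  cal <- solve_class_conditionals(target_or_plasma, target_or_apoe,
                                  base$prevalence,
                                  plasma_marginal_mean, plasma_marginal_sd,
                                  carrier_marginal)
  cfg <- base
  cfg$carrier_rate_pos <- cal$carrier_rate_pos
  cfg$carrier_rate_neg <- cal$carrier_rate_neg
  cfg$plasma_mean_neg <- cal$plasma_mean_neg
  cfg$plasma_mean_pos <- cal$plasma_mean_pos
  cfg$plasma_sd <- cal$plasma_sd
  validate_generator_config(cfg)

  pop_auc <- population_auc(cfg)
  mc_auc <- NA_real_
  if (mc_check) {
    mc_auc <- with_seed(seed, {
      mean(vapply(seq_len(n_sim), function(i) {
        co <- generate_cohort_unseeded(cfg)
        m <- fit_risk_model(co, variant = "full")
        auc(predict_risk(m, co), co$pet_status)
      }, numeric(1)))
    })
    if (abs(mc_auc - target_auc) > auc_tol) {
      stop_config(paste0(
        "calibration failure: mean fitted AUC %.4f at n = %d misses target %.3f ",
        "by more than %.3f (population AUC %.4f). The odds-ratio targets and ",
        "marginal constraints fully determine the AUC; revise the targets."),
        mc_auc, as.integer(base$n), target_auc, auc_tol, pop_auc)
    }
  }
  attr(cfg, "calibration") <- list(
    targets = c(auc = target_auc, or_plasma = target_or_plasma,
                or_apoe = target_or_apoe),
    population_auc = pop_auc, mc_mean_auc = mc_auc,
    separation = cal$separation)
  cfg
}
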