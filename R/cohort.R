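COHORT_COLUMNS <- c("id", "group", "age", "sex", "education",
                    "apoe_e4_count", "plasma_ab4240", "pet_suvr", "pet_status")

#' Generate a synthetic cognitively unimpaired cohort
#'
#' Draws `config$n` participants. PET status is Bernoulli with the configured
#' prevalence (optionally group-conditional and/or age-dependent); APOE e4
#' carriage, plasma A-beta 42/40 and PET SUVR are drawn from class-conditional
#' distributions given PET status; age, sex, education and diagnostic group
#' are drawn from the configured marginals. Deterministic given
#' `config$seed`.
#'
#' When `age_beta != 0` the PET-status intercept is re-solved on the sampled
#' ages so the marginal prevalence is preserved.
#'
#' @param config A [generator_config()].
#' @return A `data.frame` of class `cohort` with columns
#'   `id, group, age, sex, education, apoe_e4_count, plasma_ab4240, pet_suvr,
#'   pet_status` (`pet_status` coded 0/1).
#' @examples
#' cohort <- generate_cohort(generator_config(n = 200, seed = 7))
#' table(cohort$pet_status)
#' @export
generate_cohort <- function(config) {
  validate_generator_config(config)
  with_seed(config$seed, generate_cohort_unseeded(config))
}

# body of the generator; uses the current RNG stream
generate_cohort_unseeded <- function(config) {
  n <- as.integer(config$n)

  group <- ifelse(stats::runif(n) < config$scd_fraction, "SCD", "CN")

  mu_age <- truncnorm_location_for_mean(config$age_mean, config$age_sd,
                                        config$age_min, config$age_max)
  age <- rtruncnorm(n, mu_age, config$age_sd, config$age_min, config$age_max)

  # linear predictor for PET status
  if (is.null(config$group_prevalence)) {
    eta <- rep(stats::qlogis(config$prevalence), n)
  } else {
    eta <- stats::qlogis(unname(config$group_prevalence[group]))
  }
  if (config$age_beta != 0) {
    zage <- (age - mean(age)) / stats::sd(age)
    # preserve the marginal prevalence by re-solving the intercept shift
    target <- mean(stats::plogis(eta))
    shift <- stats::uniroot(
      function(a) mean(stats::plogis(eta + a + config$age_beta * zage)) - target,
      interval = c(-10, 10), tol = 1e-10)$root
    eta <- eta + shift + config$age_beta * zage
  }
  pet_status <- as.integer(stats::runif(n) < stats::plogis(eta))

  carrier_rate <- ifelse(pet_status == 1L, config$carrier_rate_pos,
                         config$carrier_rate_neg)
  carrier <- as.integer(stats::runif(n) < carrier_rate)
  apoe_e4_count <- carrier +
    as.integer(carrier == 1L & stats::runif(n) < config$homozygote_fraction)

  plasma_mean <- ifelse(pet_status == 1L, config$plasma_mean_pos,
                        config$plasma_mean_neg)
  plasma_ab4240 <- stats::rnorm(n, plasma_mean, config$plasma_sd)
  plasma_ab4240 <- pmax(plasma_ab4240, 1e-6) # ratio is physically positive

  pet_suvr <- stats::rnorm(
    n,
    ifelse(pet_status == 1L, config$suvr_mean_pos, config$suvr_mean_neg),
    ifelse(pet_status == 1L, config$suvr_sd_pos, config$suvr_sd_neg))

  sex <- ifelse(stats::runif(n) < config$female_fraction, "female", "male")
  education <- rtruncnorm(n, config$education_mean, config$education_sd, 0, Inf)

  cohort <- data.frame(
    id = sprintf("P%05d", seq_len(n)),
    group = group, age = age, sex = sex, education = education,
    apoe_e4_count = apoe_e4_count, plasma_ab4240 = plasma_ab4240,
    pet_suvr = pet_suvr, pet_status = pet_status,
    stringsAsFactors = FALSE)
  class(cohort) <- c("cohort", "data.frame")
  attr(cohort, "suvr_cutoff") <- config$suvr_cutoff
  cohort
}

#' Validate a cohort table
#'
#' Checks column presence, types and field invariants (age at the study
#' minimum or above, e4 allele count in 0..2, positive plasma ratio, 0/1 PET
#' status). Disagreement between `pet_status` and thresholded `pet_suvr` is
#' reported as a warning, not an error: SUVR is a noisy measurement of the
#' latent amyloid class, so a small discordant fraction is expected.
#'
#' @param cohort A data frame with the cohort columns.
#' @param suvr_cutoff SUVR positivity threshold used for the consistency check.
#' @param age_min Minimum allowed age.
#' @return The validated cohort (invisibly), classed as `cohort`.
#' @export
validate_cohort <- function(cohort, suvr_cutoff = 0.742, age_min = 60) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0)
    stop_config("cohort must be a non-empty data frame")
  missing_cols <- setdiff(COHORT_COLUMNS, names(cohort))
  if (length(missing_cols))
    stop_config("cohort is missing column(s): %s", paste(missing_cols, collapse = ", "))
  for (col in c("age", "education", "plasma_ab4240", "pet_suvr")) {
    if (!is.numeric(cohort[[col]]))
      stop_config("column `%s` must be numeric", col)
  }
  if (!all(cohort$group %in% c("CN", "SCD")))
    stop_config("column `group` must contain only CN/SCD")
  if (!all(cohort$sex %in% c("male", "female")))
    stop_config("column `sex` must contain only male/female")
  if (!all(cohort$apoe_e4_count %in% 0:2))
    stop_config("column `apoe_e4_count` must be an allele count in {0, 1, 2}")
  if (any(cohort$age < age_min))
    stop_config("column `age` contains values below the study minimum of %g", age_min)
  if (any(cohort$plasma_ab4240 <= 0))
    stop_config("column `plasma_ab4240` must be positive")
  if (!all(cohort$pet_status %in% c(0L, 1L)))
    stop_config("column `pet_status` must be coded 0/1")
  disc <- mean((cohort$pet_suvr > suvr_cutoff) != (cohort$pet_status == 1L))
  if (disc > 0.05)
    warning(sprintf(
      "%.1f%% of participants have pet_status discordant with pet_suvr > %.3f",
      100 * disc, suvr_cutoff), call. = FALSE)
  if (!inherits(cohort, "cohort")) class(cohort) <- c("cohort", "data.frame")
  invisible(cohort)
}

#' Write / read a cohort CSV
#'
#' `write_cohort()` writes the standard nine-column cohort CSV (UTF-8, `.`
#' decimal, `pet_status` coded 0/1). `read_cohort()` reads and validates it;
#' if `pet_status` is absent but `pet_suvr` present, status is derived by
#' thresholding at `suvr_cutoff` and a message is emitted. Unknown columns or
#' non-numeric fields are rejected with the offending column named.
#'
#' @param cohort A cohort data frame.
#' @param path File path.
#' @param suvr_cutoff SUVR threshold used when deriving a missing `pet_status`.
#' @return `read_cohort()` returns a validated `cohort`; `write_cohort()`
#'   returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(as.data.frame(cohort)[, COHORT_COLUMNS],
                   path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, suvr_cutoff = 0.742) {
  if (!file.exists(path)) stop_config("no such file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  extra <- setdiff(names(df), COHORT_COLUMNS)
  if (length(extra))
    stop_config("unexpected column(s) in cohort file: %s", paste(extra, collapse = ", "))
  if (!"pet_status" %in% names(df)) {
    if (!"pet_suvr" %in% names(df))
      stop_config("cohort file has neither `pet_status` nor `pet_suvr`")
    if (!is.numeric(df$pet_suvr)) stop_config("column `pet_suvr` must be numeric")
    df$pet_status <- as.integer(df$pet_suvr > suvr_cutoff)
    message(sprintf("pet_status absent: derived from pet_suvr > %.3f", suvr_cutoff))
  }
  if (!is.numeric(df$pet_status) && !is.integer(df$pet_status))
    stop_config("column `pet_status` must be numeric 0/1")
  df$pet_status <- as.integer(df$pet_status)
  df$apoe_e4_count <- as.integer(df$apoe_e4_count)
  validate_cohort(df, suvr_cutoff = suvr_cutoff)
}
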