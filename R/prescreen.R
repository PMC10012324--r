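#' Invitation masks from predicted risk
#'
#' `invite_relative()` invites the top `(1 - q)` fraction of a screened
#' population ranked by predicted risk: exactly `ceiling((1 - q) * n)`
#' participants, boundary ties broken by stable input order. `q = 0` invites
#' everyone (no pre-screening). `invite_absolute()` invites every participant
#' whose predicted probability is at least the cutoff `c`; `c = 0` invites
#' everyone.
#'
#' @param risks Numeric vector of predicted PET-positive probabilities.
#' @param q Percentile threshold in \[0, 1) (relative mode).
#' @param cutoff Absolute probability cutoff in \[0, 1).
#' @return Logical invitation mask of the same length as `risks`.
#' @examples
#' invite_relative(c(0.1, 0.2, 0.3, 0.4), q = 0.5)
#' invite_absolute(c(0.2, 0.5, 0.8), cutoff = 0.5)
#' @export
invite_relative <- function(risks, q) {
  n <- length(risks)
  if (n == 0) stop_config("`risks` must be non-empty")
  if (!is_probability(q) || q >= 1) stop_config("`q` must lie in [0, 1)")
  m <- ceiling((1 - q) * n)
  ord <- order(-risks) # radix sort: stable, so boundary ties keep input order
  mask <- logical(n)
  mask[ord[seq_len(m)]] <- TRUE
  mask
}

#' @rdname invite_relative
#' @export
invite_absolute <- function(risks, cutoff) {
  if (length(risks) == 0) stop_config("`risks` must be non-empty")
  if (!is_probability(cutoff) || cutoff >= 1)
    stop_config("`cutoff` must lie in [0, 1)")
  risks >= cutoff
}

#' PET-positive yield among invited participants
#'
#' The positive predictive value of the invitation rule: the fraction of
#' invited participants who are truly PET-positive. At full invitation this
#' equals the cohort prevalence.
#'
#' @param mask Logical invitation mask.
#' @param pet_status 0/1 PET status vector.
#' @return Yield (PPV) in \[0, 1\].
#' @export
yield_ppv <- function(mask, pet_status) {
  if (length(mask) != length(pet_status))
    stop_config("`mask` and `pet_status` differ in length")
  if (!any(mask))
    stop_config("empty invitation: yield is undefined")
  mean(pet_status[mask] == 1)
}

#' Tests required to recruit a target number of PET-positive participants
#'
#' Given the yield among invited participants and the invited fraction,
#' computes the number of confirmatory PET scans and first-stage plasma tests
#' needed to enrol `n_target` PET-positive participants. Counts are rounded
#' up (partial tests are impossible): `n_pet = ceiling(n_target / ppv)`,
#' `n_plasma = ceiling(n_pet / invited_fraction)`. With full invitation
#' (`invited_fraction = 1`, i.e. no pre-screening) no plasma tests are
#' performed and `n_plasma` is 0.
#'
#' @param ppv Yield among invited (must be > 0).
#' @param invited_fraction Fraction of the screened population invited, in
#'   (0, 1\].
#' @param n_target Number of PET-positive participants to recruit.
#' @return Named vector `c(n_pet, n_plasma)`.
#' @examples
#' required_tests(0.286, 1, 500)    # no pre-screening: 1749 PET scans
#' required_tests(0.546, 0.5, 500)  # 50th-percentile cutoff
#' @export
required_tests <- function(ppv, invited_fraction, n_target = 500) {
  if (!is.numeric(ppv) || ppv <= 0)
    stop_config("recruitment impossible: yield (ppv) must be positive")
  if (!is.numeric(invited_fraction) || invited_fraction <= 0 || invited_fraction > 1)
    stop_config("`invited_fraction` must lie in (0, 1]")
  if (n_target < 1) stop_config("`n_target` must be >= 1")
  n_pet <- ceiling(n_target / ppv)
  n_plasma <- if (invited_fraction == 1) 0 else ceiling(n_pet / invited_fraction)
  c(n_pet = n_pet, n_plasma = n_plasma)
}

#' Sweep invitation thresholds with bootstrap uncertainty
#'
#' For each threshold on the grid, computes the invited fraction, PET-positive
#' yield (PPV) and required plasma/PET test counts, both as plug-in estimates
#' on the full cohort and as bootstrap means with percentile CIs. Each
#' bootstrap resample refits the risk model and, in relative mode, recomputes
#' the percentile cutoffs within the resample. The p-value compares the
#' resample's yield at each threshold with the same resample's yield at full
#' invitation (paired, two-sided, floored at 1/B).
#'
#' Thresholds yielding an empty invitation produce `NA` rows with a warning.
#'
#' @param cohort A cohort data frame.
#' @param variant Model variant, see [fit_risk_model()].
#' @param mode `"relative"` (percentile threshold) or `"absolute"`
#'   (probability cutoff).
#' @param grid Ascending threshold grid in \[0, 1).
#' @param n_target PET-positive recruitment target.
#' @param B Bootstrap replicates (0 = plug-in only).
#' @param seed RNG seed for the bootstrap.
#' @param ridge Ridge penalty passed to the model fits.
#' @return A `data.frame` of class `screening_result` with columns `mode,
#'   threshold, invited_fraction, ppv, ppv_boot, ppv_lo, ppv_hi, p_vs_none,
#'   n_pet, n_pet_boot, n_plasma, n_plasma_boot`. Bootstrap replicate
#'   matrices are attached as attribute `"replicates"` for downstream cost
#'   analysis.
#' @examples
#' co <- generate_cohort(generator_config(seed = 7))
#' screen_sweep(co, mode = "relative", grid = c(0, 0.5), B = 50, seed = 1)
#' @export
screen_sweep <- function(cohort, variant = "full",
                         mode = c("relative", "absolute"),
                         grid = seq(0, 0.90, by = 0.05),
                         n_target = 500, B = 1000, seed = NULL, ridge = 0) {
  mode <- match.arg(mode)
  if (is.unsorted(grid)) stop_config("`grid` must be sorted ascending")
  if (any(grid < 0 | grid >= 1)) stop_config("grid values must lie in [0, 1)")

  model <- fit_risk_model(cohort, variant = variant, ridge = ridge)
  risks <- predict_risk(model, cohort)
  status <- as.integer(cohort$pet_status)

  point <- sweep_once(risks, status, mode, grid, n_target)
  if (anyNA(point$ppv))
    warning("some thresholds produced empty invitations; reported as NA",
            call. = FALSE)

  G <- length(grid)
  res <- data.frame(
    mode = mode, threshold = grid,
    invited_fraction = point$f, ppv = point$ppv,
    ppv_boot = NA_real_, ppv_lo = NA_real_, ppv_hi = NA_real_,
    p_vs_none = NA_real_,
    n_pet = point$n_pet, n_pet_boot = NA_real_,
    n_plasma = point$n_plasma, n_plasma_boot = NA_real_)

  if (B > 0) {
    stat <- function(co) {
      m <- fit_risk_model(co, variant = variant, ridge = ridge)
      r <- predict_risk(m, co)
      s <- sweep_once(r, as.integer(co$pet_status), mode, grid, n_target)
      c(s$ppv, s$n_pet, s$n_plasma)
    }
    bd <- bootstrap_statistic(cohort, stat, B = B, seed = seed,
                              require_both_classes = TRUE, allow_na = TRUE)
    ppv_m <- bd$values[, seq_len(G), drop = FALSE]
    npet_m <- bd$values[, G + seq_len(G), drop = FALSE]
    npl_m <- bd$values[, 2 * G + seq_len(G), drop = FALSE]

    res$ppv_boot <- colMeans(ppv_m, na.rm = TRUE)
    ci <- boot_ci(ppv_m)
    res$ppv_lo <- ci[1, ]
    res$ppv_hi <- ci[2, ]
    res$n_pet_boot <- colMeans(npet_m, na.rm = TRUE)
    res$n_plasma_boot <- colMeans(npl_m, na.rm = TRUE)
    # paired comparison with the same resample's no-pre-screening yield
    base_ppv <- if (any(grid == 0)) ppv_m[, which(grid == 0)[1]] else
      vapply(seq_len(B), function(b) NA_real_, numeric(1))
    res$p_vs_none <- vapply(seq_len(G), function(g) {
      if (all(is.na(base_ppv))) return(NA_real_)
      boot_pvalue(ppv_m[, g] - base_ppv, null = 0)
    }, numeric(1))
    attr(res, "replicates") <- list(ppv = ppv_m, n_pet = npet_m,
                                    n_plasma = npl_m, discarded = bd$discarded)
  }
  attr(res, "n_target") <- n_target
  attr(res, "B") <- B
  attr(res, "seed") <- seed
  attr(res, "variant") <- variant
  attr(res, "prevalence") <- mean(status)
  class(res) <- c("screening_result", "data.frame")
  res
}

# point computation of f / ppv / counts over a grid; NA for empty invitations
sweep_once <- function(risks, status, mode, grid, n_target) {
  n <- length(risks)
  f <- ppv <- n_pet <- n_plasma <- rep(NA_real_, length(grid))
  for (i in seq_along(grid)) {
    mask <- if (mode == "relative") invite_relative(risks, grid[i])
            else invite_absolute(risks, grid[i])
    if (!any(mask)) next
    f[i] <- mean(mask)
    ppv[i] <- yield_ppv(mask, status)
    if (ppv[i] > 0) {
      ct <- required_tests(ppv[i], f[i], n_target)
      n_pet[i] <- ct[["n_pet"]]
      n_plasma[i] <- ct[["n_plasma"]]
    }
  }
  list(f = f, ppv = ppv, n_pet = n_pet, n_plasma = n_plasma)
}
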