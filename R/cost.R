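#' Total recruitment cost in plasma-test units
#'
#' Cost of the two-stage recruitment: one unit per plasma test plus `r` units
#' per PET scan, where `r` is the PET-to-plasma cost ratio. Only the ratio
#' matters for relative comparisons; `plasma_unit_cost` rescales both terms
#' by a common factor.
#'
#' @param n_plasma,n_pet Test counts (>= 0).
#' @param r PET-to-plasma cost ratio (> 0).
#' @param plasma_unit_cost Cost of one plasma test (default 1).
#' @return Total cost (vectorized over inputs).
#' @examples
#' total_cost(1850, 926, 8)
#' @export
total_cost <- function(n_plasma, n_pet, r, plasma_unit_cost = 1) {
  if (any(n_plasma < 0) || any(n_pet < 0))
    stop_config("test counts must be nonnegative")
  if (any(r <= 0)) stop_config("cost ratio `r` must be positive")
  plasma_unit_cost * (n_plasma + n_pet * r)
}

#' Percentage cost change of pre-screening versus no pre-screening
#'
#' The plug-in cost difference
#' `100 * (total - baseline) / baseline`, where the baseline scenario scans
#' an unscreened population (`baseline_n_pet` scans, zero plasma cost).
#' Negative values are savings.
#'
#' @param n_plasma,n_pet Test counts under pre-screening.
#' @param baseline_n_pet PET scans required without pre-screening.
#' @param r PET-to-plasma cost ratio.
#' @param plasma_unit_cost Common cost scale (cancels out).
#' @return Percentage change (vectorized).
#' @examples
#' delta_cost_pct(1850, 926, 1749, r = 8)
#' @export
delta_cost_pct <- function(n_plasma, n_pet, baseline_n_pet, r,
                           plasma_unit_cost = 1) {
  if (any(baseline_n_pet <= 0))
    stop_config("baseline PET count must be positive")
  tc <- total_cost(n_plasma, n_pet, r, plasma_unit_cost)
  bc <- total_cost(0, baseline_n_pet, r, plasma_unit_cost)
  100 * (tc - bc) / bc
}

#' Cost sweep across thresholds and PET-to-plasma cost ratios
#'
#' Expands a [screen_sweep()] result into a threshold-by-ratio table of total
#' recruitment costs and percentage savings versus the no-pre-screening
#' baseline (the threshold-0 scenario of the same sweep). When the sweep
#' carries bootstrap replicates, the cost difference is computed within each
#' resample — both arms from the same resample's counts (paired) — and
#' summarized by the bootstrap mean, percentile CI and two-sided p-value
#' against zero. Rows whose CI crosses zero are flagged in `significant`.
#'
#' @param screening A `screening_result` from [screen_sweep()] whose grid
#'   includes threshold 0.
#' @param ratios PET-to-plasma cost ratios (default 4, 8, 16).
#' @return A `data.frame` of class `cost_result` with columns `mode,
#'   threshold, ratio, total_cost, baseline_cost, delta_pct, delta_boot,
#'   delta_lo, delta_hi, p_value, significant`.
#' @examples
#' co <- generate_cohort(generator_config(seed = 7))
#' sc <- screen_sweep(co, mode = "relative", grid = c(0, 0.5), B = 50, seed = 1)
#' cost_sweep(sc, ratios = c(4, 16))
#' @export
cost_sweep <- function(screening, ratios = c(4, 8, 16)) {
  stopifnot(inherits(screening, "screening_result"))
  if (any(ratios <= 0)) stop_config("cost ratios must be positive")
  i0 <- which(screening$threshold == 0)
  if (length(i0) == 0)
    stop_config("the screening grid must include threshold 0 (the no-pre-screening baseline)")
  i0 <- i0[1]
  if (is.na(screening$ppv[i0]) || screening$ppv[i0] <= 0)
    stop_config("baseline yield is zero or undefined; cost comparison impossible")
  reps <- attr(screening, "replicates")

  rows <- list()
  for (r in ratios) {
    base_cost <- total_cost(0, screening$n_pet[i0], r)
    tc <- total_cost(ifelse(is.na(screening$n_plasma), NA, screening$n_plasma),
                     screening$n_pet, r)
    delta <- 100 * (tc - base_cost) / base_cost
    out <- data.frame(
      mode = screening$mode, threshold = screening$threshold, ratio = r,
      total_cost = tc, baseline_cost = base_cost, delta_pct = delta,
      delta_boot = NA_real_, delta_lo = NA_real_, delta_hi = NA_real_,
      p_value = NA_real_, significant = NA)
    if (!is.null(reps)) {
      base_b <- reps$n_pet[, i0] * r
      for (g in seq_len(nrow(screening))) {
        d_b <- 100 * ((reps$n_plasma[, g] + reps$n_pet[, g] * r) - base_b) / base_b
        d_b <- d_b[is.finite(d_b)]
        if (length(d_b) == 0) next
        ci <- boot_ci(d_b)
        out$delta_boot[g] <- mean(d_b)
        out$delta_lo[g] <- ci[1]
        out$delta_hi[g] <- ci[2]
        out$p_value[g] <- boot_pvalue(d_b, null = 0)
        out$significant[g] <- ci[1] > 0 || ci[2] < 0
      }
    }
    rows[[length(rows) + 1]] <- out
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "n_target") <- attr(screening, "n_target")
  class(res) <- c("cost_result", "data.frame")
  res
}
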