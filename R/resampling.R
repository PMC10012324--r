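#' Bootstrap a cohort-level statistic
#'
#' Draws `B` participant-level resamples with replacement and evaluates
#' `statistic_fn` on each (refitting any model inside the statistic).
#' Resamples on which the outcome has a single class (when
#' `require_both_classes`) or the statistic is non-finite are discarded and
#' redrawn, up to `10 * B` discards.
#'
#' @param cohort A cohort data frame.
#' @param statistic_fn Function mapping a cohort to a finite scalar or a
#'   fixed-length numeric vector.
#' @param B Number of bootstrap replicates.
#' @param seed RNG seed.
#' @param require_both_classes Require both PET classes in each resample
#'   (only applied when the cohort has a `pet_status` column).
#' @param allow_na Tolerate `NA` elements in vector-valued statistics (e.g.
#'   thresholds with empty invitations) instead of discarding the resample.
#' @return An object of class `bootstrap_distribution`: a list with
#'   `statistic` (name), `B`, `values` (length-B vector, or B-row matrix for
#'   vector statistics), `seed`, `discarded`.
#' @seealso [boot_ci()], [boot_pvalue()]
#' @examples
#' co <- generate_cohort(generator_config(n = 120, seed = 2))
#' bd <- bootstrap_statistic(co, function(x) mean(x$age), B = 200, seed = 9)
#' boot_ci(bd)
#' @export
bootstrap_statistic <- function(cohort, statistic_fn, B = 1000, seed = NULL,
                                require_both_classes = TRUE, allow_na = FALSE) {
  n <- nrow(cohort)
  if (is.null(n) || n < 2) stop_config("cohort must have at least 2 rows")
  check_classes <- require_both_classes && "pet_status" %in% names(cohort)
  with_seed(seed, {
    values <- vector("list", B)
    b <- 0L
    discarded <- 0L
    while (b < B) {
      idx <- sample.int(n, n, replace = TRUE)
      if (check_classes && length(unique(cohort$pet_status[idx])) < 2L) {
        discarded <- discarded + 1L
        if (discarded > 10L * B)
          stop_config("more than %d degenerate bootstrap resamples discarded", 10L * B)
        next
      }
      val <- statistic_fn(cohort[idx, , drop = FALSE])
      bad <- !is.numeric(val) ||
        (if (allow_na) FALSE else anyNA(val) || any(!is.finite(val)))
      if (bad) {
        discarded <- discarded + 1L
        if (discarded > 10L * B)
          stop_config("more than %d degenerate bootstrap resamples discarded", 10L * B)
        next
      }
      b <- b + 1L
      values[[b]] <- val
    }
    lens <- lengths(values)
    vals <- if (all(lens == 1L)) unlist(values) else do.call(rbind, values)
    structure(list(statistic = deparse(substitute(statistic_fn))[1],
                   B = B, values = vals, seed = seed, discarded = discarded),
              class = "bootstrap_distribution")
  })
}

#' Percentile confidence interval of a bootstrap distribution
#'
#' @param boot A `bootstrap_distribution` (or bare numeric vector of
#'   replicates).
#' @param level Confidence level.
#' @return Named vector `c(lower, upper)` (per column for matrix-valued
#'   replicates).
#' @export
boot_ci <- function(boot, level = 0.95) {
  v <- if (inherits(boot, "bootstrap_distribution")) boot$values else boot
  a <- (1 - level) / 2
  if (is.matrix(v)) {
    apply(v, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE, na.rm = TRUE)
  } else {
    stats::setNames(stats::quantile(v, c(a, 1 - a), names = FALSE, na.rm = TRUE),
                    c("lower", "upper"))
  }
}

#' Two-sided bootstrap p-value against a null value
#'
#' Sign-fraction convention: `2 * min(P(hat <= null), P(hat >= null))`,
#' floored at `1/B` (a bootstrap distribution entirely on one side of the
#' null cannot yield p = 0).
#'
#' @inheritParams boot_ci
#' @param null Null value of the statistic.
#' @return p-value in \[1/B, 1\].
#' @export
boot_pvalue <- function(boot, null = 0) {
  v <- if (inherits(boot, "bootstrap_distribution")) boot$values else boot
  v <- v[is.finite(v)]
  p <- 2 * min(mean(v <= null), mean(v >= null))
  max(min(p, 1), 1 / length(v))
}

#' @export
print.bootstrap_distribution <- function(x, ...) {
  cat(sprintf("<bootstrap_distribution> B = %d (%d resamples discarded)\n",
              x$B, x$discarded))
  if (!is.matrix(x$values)) {
    ci <- boot_ci(x)
    cat(sprintf("  mean %.4f, 95%% CI (%.4f, %.4f)\n",
                mean(x$values), ci[1], ci[2]))
  } else {
    cat(sprintf("  vector-valued statistic of length %d\n", ncol(x$values)))
  }
  invisible(x)
}

#' Cross-validated out-of-sample AUC
#'
#' Stratified k-fold cross-validation of the risk model: folds are assigned
#' separately within PET-positive and PET-negative participants, the model is
#' refit on each training set (standardization recomputed on the training
#' fold only), risks are predicted on the held-out fold, and the AUC is
#' pooled over all held-out predictions. The CI is the percentile interval
#' over `repeats` independent fold assignments.
#'
#' @param cohort A cohort data frame.
#' @param variant Model variant, see [fit_risk_model()].
#' @param k Number of folds (k = n gives leave-one-out).
#' @param repeats Number of repeated fold assignments for the CI.
#' @param seed RNG seed.
#' @return A list of class `performance_estimate`: `auc` (mean pooled AUC
#'   over repeats), `ci_low`, `ci_high`, `method = "cv"`, `k`, `repeats`,
#'   `per_repeat`.
#' @export
cross_validate <- function(cohort, variant = "full", k = 5, repeats = 20,
                           seed = NULL) {
  n <- nrow(cohort)
  loo <- k >= n
  if (!loo && n < 2 * k)
    stop_config("need n >= 2k observations for %d folds", k)
  y <- as.integer(cohort$pet_status)
  if (length(unique(y)) < 2) stop_config("both PET classes required")
  if (loo) { k <- n; repeats <- 1L }

  with_seed(seed, {
    one_repeat <- function() {
      if (loo) {
        folds <- seq_len(n)
      } else {
        folds <- integer(n)
        for (cls in c(0L, 1L)) {
          idx <- which(y == cls)
          folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
        }
      }
      pred <- rep(NA_real_, n)
      for (f in seq_len(k)) {
        test <- folds == f
        if (!any(test)) next
        train_y <- y[!test]
        if (length(unique(train_y)) < 2)
          stop_config("training fold %d lost a PET class; reduce k", f)
        m <- fit_risk_model(cohort[!test, , drop = FALSE], variant = variant)
        pred[test] <- predict_risk(m, cohort[test, , drop = FALSE])
      }
      auc(pred, y)
    }
    per_repeat <- vapply(seq_len(repeats), function(i) one_repeat(), numeric(1))
    ci <- if (repeats > 1) boot_ci(per_repeat) else c(per_repeat, per_repeat)
    structure(list(auc = mean(per_repeat),
                   ci_low = unname(ci[1]), ci_high = unname(ci[2]),
                   method = "cv", k = k, repeats = repeats,
                   per_repeat = per_repeat),
              class = "performance_estimate")
  })
}

#' @export
print.performance_estimate <- function(x, ...) {
  cat(sprintf("<performance_estimate> %s AUC = %.3f, 95%% CI (%.3f, %.3f)\n",
              x$method, x$auc, x$ci_low, x$ci_high))
  invisible(x)
}
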