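MODEL_VARIANTS <- list(
  full        = c("plasma_neg", "apoe_carrier", "age"),
  plasma_apoe = c("plasma_neg", "apoe_carrier"),
  apoe_age    = c("apoe_carrier", "age")
)

#' Build the design matrix for a model variant
#'
#' Converts a cohort into the predictor matrix and outcome used by the
#' logistic risk model. The plasma A-beta 42/40 ratio is negated (so higher
#' values indicate more amyloid pathology) and z-scored; age is z-scored; the
#' APOE e4 allele count is collapsed to a 0/1 carrier flag (at least one e4
#' allele). Continuous predictors are standardized with the supplied
#' `standardization` parameters when given (e.g. at prediction time), else
#' with the cohort's own mean/SD.
#'
#' @param cohort A cohort data frame.
#' @param variant One of `"full"` (plasma + APOE + age), `"plasma_apoe"`,
#'   `"apoe_age"`.
#' @param standardization Optional list of per-predictor `c(mean, sd)` as
#'   stored in a fitted model.
#' @return A list with `X` (numeric matrix, no intercept column), `y` (0/1
#'   outcome), and `standardization`.
#' @export
preprocess <- function(cohort, variant = c("full", "plasma_apoe", "apoe_age"),
                       standardization = NULL) {
  variant <- match.arg(variant)
  vars <- MODEL_VARIANTS[[variant]]
  need <- c("pet_status",
            if ("plasma_neg" %in% vars) "plasma_ab4240",
            if ("apoe_carrier" %in% vars) "apoe_e4_count",
            if ("age" %in% vars) "age")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols))
    stop_config("cohort is missing column(s) required by variant '%s': %s",
                variant, paste(missing_cols, collapse = ", "))

  raw <- list()
  if ("plasma_neg" %in% vars) raw$plasma_neg <- -cohort$plasma_ab4240
  if ("age" %in% vars) raw$age <- cohort$age

  std <- standardization
  if (is.null(std)) {
    std <- lapply(raw, function(v) c(mean = mean(v), sd = stats::sd(v)))
    for (nm in names(std)) {
      if (!is.finite(std[[nm]]["sd"]) || std[[nm]]["sd"] <= 0)
        stop_config("continuous predictor `%s` has zero variance; cannot standardize", nm)
    }
  }

  cols <- lapply(vars, function(v) {
    if (v == "apoe_carrier") as.numeric(cohort$apoe_e4_count >= 1)
    else (raw[[v]] - std[[v]]["mean"]) / std[[v]]["sd"]
  })
  X <- do.call(cbind, cols)
  colnames(X) <- vars
  list(X = X, y = as.integer(cohort$pet_status), standardization = std)
}

#' Fit a logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit with Newton/IRLS steps and step-halving.
#' Convergence is declared when the maximum absolute score (gradient of the
#' log-likelihood) falls below `tol`. If the fit diverges — the signature of
#' complete separation, common in small bootstrap resamples — a small ridge
#' penalty is applied as a fallback and the fit is flagged.
#'
#' @param X Predictor matrix (no intercept column; one is added).
#' @param y 0/1 outcome, both classes present.
#' @param ridge Nonnegative ridge penalty on non-intercept coefficients.
#' @param tol Score-norm convergence tolerance.
#' @param max_iter Maximum IRLS iterations.
#' @return A list: `coefficients` (named, `(Intercept)` first), `converged`,
#'   `iterations`, `score_norm`, `separation` (logical), `ridge` (penalty
#'   actually used).
#' @examples
#' x <- matrix(rnorm(200), ncol = 1)
#' y <- rbinom(100, 1, plogis(x))
#' fit_logistic(x, y)$coefficients
#' @export
fit_logistic <- function(X, y, ridge = 0, tol = 1e-8, max_iter = 100) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop_config("`y` must be coded 0/1")
  if (length(unique(y)) < 2) stop_config("`y` contains a single class; cannot fit")
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop_config("rows of `X` must match length of `y`")

  fit <- irls(cbind(`(Intercept)` = 1, X), y, ridge, tol, max_iter)
  separation <- !fit$converged || max(abs(fit$beta[-1])) > 15
  if (separation && ridge == 0) {
    guard <- 1e-8
    fit2 <- irls(cbind(`(Intercept)` = 1, X), y, guard, tol, max_iter)
    fit2$separation <- TRUE
    fit2$ridge <- guard
    return(finish_fit(fit2))
  }
  fit$separation <- separation
  fit$ridge <- ridge
  finish_fit(fit)
}

finish_fit <- function(fit) {
  list(coefficients = fit$beta, converged = fit$converged,
       iterations = fit$iterations, score_norm = fit$score_norm,
       separation = isTRUE(fit$separation), ridge = fit$ridge)
}

irls <- function(Xi, y, ridge, tol, max_iter) {
  p <- ncol(Xi)
  beta <- numeric(p)
  names(beta) <- colnames(Xi)
  pen <- c(0, rep(ridge, p - 1)) # intercept unpenalized
  loglik <- function(b) {
    eta <- drop(Xi %*% b)
    sum(y * eta - log1p(exp(eta))) - sum(pen * b^2) / 2
  }
  ll <- loglik(beta)
  score_norm <- Inf
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    eta <- drop(Xi %*% beta)
    mu <- stats::plogis(eta)
    score <- drop(crossprod(Xi, y - mu)) - pen * beta
    score_norm <- max(abs(score))
    if (score_norm < tol) break
    w <- pmax(mu * (1 - mu), 1e-12)
    H <- crossprod(Xi * w, Xi) + diag(pen, p)
    step <- tryCatch(solve(H, score), error = function(e) NULL)
    if (is.null(step)) break
    # step-halving to guarantee ascent
    s <- 1
    repeat {
      cand <- beta + s * step
      llc <- loglik(cand)
      if (is.finite(llc) && llc >= ll - 1e-12) break
      s <- s / 2
      if (s < 1e-10) { cand <- beta; llc <- ll; break }
    }
    beta <- cand
    ll <- llc
  }
  list(beta = beta, converged = score_norm < tol, iterations = iter,
       score_norm = score_norm)
}

#' Fit the amyloid-PET risk model on a cohort
#'
#' Preprocesses the cohort for the chosen predictor variant and fits the
#' logistic model. Coefficients for continuous predictors are on the per-SD
#' scale (the standardization parameters are stored in the model and reused
#' at prediction time).
#'
#' @inheritParams preprocess
#' @param subset Optional logical or integer index restricting the cohort
#'   (e.g. CN-only participants) before fitting.
#' @param ridge Passed to [fit_logistic()].
#' @return An object of class `risk_model`.
#' @examples
#' cohort <- generate_cohort(generator_config(n = 300, seed = 3))
#' m <- fit_risk_model(cohort)
#' m
#' @export
fit_risk_model <- function(cohort, variant = c("full", "plasma_apoe", "apoe_age"),
                           subset = NULL, ridge = 0) {
  variant <- match.arg(variant)
  if (!is.null(subset)) cohort <- cohort[subset, , drop = FALSE]
  prep <- preprocess(cohort, variant)
  fit <- fit_logistic(prep$X, prep$y, ridge = ridge)
  structure(list(
    variant = variant,
    intercept = unname(fit$coefficients[1]),
    coefficients = fit$coefficients[-1],
    standardization = prep$standardization,
    convergence = fit[c("converged", "iterations", "score_norm",
                        "separation", "ridge")],
    n = nrow(cohort), n_pos = sum(prep$y)
  ), class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> variant '%s' fitted on n = %d (%d PET+)\n",
              x$variant, x$n, x$n_pos))
  or <- exp(x$coefficients)
  lab <- c(plasma_neg = "plasma Abeta42/40 (negated, per SD)",
           apoe_carrier = "APOE e4 carrier",
           age = "age (per SD)")
  for (nm in names(or))
    cat(sprintf("  OR %-36s %6.3f  (beta = %+.4f)\n", lab[[nm]], or[[nm]],
                x$coefficients[[nm]]))
  if (x$convergence$separation)
    cat("  note: separation detected; ridge fallback applied\n")
  invisible(x)
}

#' Predicted probability of PET positivity
#'
#' Applies a fitted [fit_risk_model()] to a cohort, standardizing continuous
#' predictors with the parameters stored in the model (not the new cohort's).
#'
#' @param model A `risk_model`.
#' @param cohort A cohort data frame with the columns the variant requires.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_risk <- function(model, cohort) {
  stopifnot(inherits(model, "risk_model"))
  prep <- preprocess(cohort, model$variant,
                     standardization = model$standardization)
  eta <- model$intercept + drop(prep$X %*% model$coefficients)
  stats::plogis(eta)
}

#' Area under the ROC curve (Mann-Whitney concordance)
#'
#' Computes P(score among positives > score among negatives) + 1/2 P(tie)
#' via midranks.
#'
#' @param scores Numeric scores (higher = more positive-like).
#' @param labels 0/1 (or logical) true labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @examples
#' auc(c(0.9, 0.2, 0.7, 0.1), c(1, 0, 1, 0))
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop_config("`scores` and `labels` differ in length")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0)
    stop_config("AUC undefined: both classes must be present")
  r <- rank(scores) # midranks give half credit to ties
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fit and compare predictor-set variants
#'
#' Fits the three predictor sets (`full`, `plasma_apoe`, `apoe_age`) on a
#' cohort (optionally restricted to a subgroup), reporting for each the
#' fitted model, in-sample AUC, and optionally bootstrap and cross-validated
#' AUC estimates.
#'
#' @param cohort A cohort data frame.
#' @param variants Character vector of variants to fit.
#' @param subset Optional subgroup restriction (logical/integer index).
#' @param B Bootstrap replicates for the AUC CI (0 skips the bootstrap).
#' @param k Cross-validation folds (0 skips CV).
#' @param seed RNG seed for bootstrap/CV.
#' @return Named list (one element per variant) of lists with `model`,
#'   `auc`, `n`, and optionally `auc_boot` ([bootstrap_statistic()] summary)
#'   and `cv` ([cross_validate()] result).
#' @export
fit_variants <- function(cohort, variants = names(MODEL_VARIANTS),
                         subset = NULL, B = 0, k = 0, seed = NULL) {
  if (!is.null(subset)) cohort <- cohort[subset, , drop = FALSE]
  variants <- match.arg(variants, names(MODEL_VARIANTS), several.ok = TRUE)
  out <- lapply(variants, function(v) {
    model <- fit_risk_model(cohort, variant = v)
    res <- list(model = model,
                auc = auc(predict_risk(model, cohort), cohort$pet_status),
                n = nrow(cohort))
    if (B > 0) {
      bd <- bootstrap_statistic(cohort, function(co) {
        m <- fit_risk_model(co, variant = v)
        auc(predict_risk(m, co), co$pet_status)
      }, B = B, seed = seed)
      res$auc_boot <- c(mean = mean(bd$values), boot_ci(bd))
    }
    if (k > 0) res$cv <- cross_validate(cohort, variant = v, k = k, seed = seed)
    res
  })
  names(out) <- variants
  out
}
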