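#' Derive a SUVR positivity cutoff by Gaussian mixture modelling
#'
#' Fits a two-component univariate Gaussian mixture (unequal variances, EM via
#' \pkg{mclust}) to a sample of SUVR values and returns the point between the
#' two component means at which the posterior membership probability equals
#' 0.5 — i.e. where the weighted component densities cross. This is the
#' convention used here for a mixture-derived positivity threshold; the
#' crossing is solved analytically from the fitted parameters (a quadratic in
#' SUVR, linear when the variances coincide).
#'
#' @param suvr_values Numeric vector of SUVR values (n >= 50, spanning both
#'   components).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @return The cutoff (a single numeric); attributes `"mixture"` carries the
#'   fitted means, SDs and weights.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(120, 0.66, 0.04), rnorm(60, 0.95, 0.10))
#' derive_suvr_cutoff(x)
#' @export
derive_suvr_cutoff <- function(suvr_values, max_iter = 1000, tol = 1e-8) {
  x <- suvr_values[is.finite(suvr_values)]
  if (length(x) < 50)
    stop_config("need at least 50 finite SUVR values (got %d)", length(x))
  if (stats::sd(x) < 1e-12)
    stop_config("SUVR values are (nearly) identical; no mixture structure to fit")

  mclustBIC <- mclust::mclustBIC # Mclust() resolves this in the caller's frame
  fit <- tryCatch(
    mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE,
                   control = mclust::emControl(itmax = max_iter, tol = tol)),
    error = function(e) NULL)
  if (is.null(fit))
    stop_config("EM fit of the two-component mixture failed")

  mu <- fit$parameters$mean
  sig <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sig) == 1L) sig <- rep(sig, 2L)
  w <- fit$parameters$pro
  if (abs(mu[1] - mu[2]) < 1e-8)
    stop_config("mixture collapsed to a single component (means %.4f, %.4f)", mu[1], mu[2])

  cutoff <- density_crossing(mu[1], sig[1], w[1], mu[2], sig[2], w[2])
  attr(cutoff, "mixture") <- list(means = unname(mu), sds = unname(sig),
                                  weights = unname(w),
                                  loglik = fit$loglik)
  cutoff
}

# Root of w1*N(x; m1, s1) = w2*N(x; m2, s2) lying between the means
# (posterior membership = 0.5 there).
density_crossing <- function(m1, s1, w1, m2, s2, w2) {
  lo <- min(m1, m2); hi <- max(m1, m2)
  # log w1 - log s1 - (x-m1)^2/(2 s1^2) = log w2 - log s2 - (x-m2)^2/(2 s2^2)
  A <- 1 / (2 * s2^2) - 1 / (2 * s1^2)
  B <- m1 / s1^2 - m2 / s2^2
  C <- m2^2 / (2 * s2^2) - m1^2 / (2 * s1^2) +
    log(w1) - log(s1) - log(w2) + log(s2)
  if (abs(A) < 1e-10) {
    if (abs(B) < 1e-14)
      stop_config("degenerate mixture: densities do not cross between the means")
    root <- -C / B
    if (root < lo || root > hi)
      stop_config("density crossing %.4f falls outside the component means", root)
    return(root)
  }
  disc <- B^2 - 4 * A * C
  if (disc < 0)
    stop_config("densities do not cross between the component means")
  roots <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  inside <- roots[roots >= lo & roots <= hi]
  if (length(inside) == 0)
    stop_config("no density crossing between the component means (roots %.4f, %.4f)",
                roots[1], roots[2])
  inside[1]
}
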