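# internal helpers shared across modules

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream; if seed is NULL the current stream is used (and advanced).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # initialise the stream so it can be restored
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Mean of a normal(mu, sd) truncated to [lo, hi]
truncnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / (stats::pnorm(b) - stats::pnorm(a))
}

# Pre-truncation location whose [lo, hi]-truncated mean equals `target`
truncnorm_location_for_mean <- function(target, sd, lo, hi) {
  stats::uniroot(function(m) truncnorm_mean(m, sd, lo, hi) - target,
                 interval = c(target - 4 * sd, target + 4 * sd),
                 tol = 1e-10)$root
}

# Inverse-CDF sampler for a normal(mu, sd) truncated to [lo, hi]
rtruncnorm <- function(n, mu, sd, lo = -Inf, hi = Inf) {
  plo <- stats::pnorm(lo, mu, sd)
  phi <- stats::pnorm(hi, mu, sd)
  stats::qnorm(stats::runif(n, plo, phi), mu, sd)
}

is_probability <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
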