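# shared fixtures: everything is generated in code at test time

default_config <- function(...) generator_config(...)

# a small deterministic cohort reused across IO / model tests
tiny_cohort <- function(n = 120, seed = 42) {
  generate_cohort(generator_config(n = n, seed = seed))
}

# brute-force pairwise AUC oracle (O(n^2)), independent of the midrank path
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# analytic mean of a normal truncated to [lo, hi]
trunc_mean_oracle <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  mu + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

# hand-built cohort from explicit columns (valid by construction)
make_cohort <- function(n, pet_status, plasma, apoe = NULL, age = NULL,
                        suvr = NULL) {
  df <- data.frame(
    id = sprintf("X%04d", seq_len(n)),
    group = rep(c("CN", "SCD"), length.out = n),
    age = if (is.null(age)) rep(73, n) + seq_len(n) %% 7 else age,
    sex = rep(c("male", "female"), length.out = n),
    education = rep(12, n),
    apoe_e4_count = if (is.null(apoe)) rep(0L, n) else as.integer(apoe),
    plasma_ab4240 = plasma,
    pet_suvr = if (is.null(suvr)) ifelse(pet_status == 1, 0.95, 0.65) else suvr,
    pet_status = as.integer(pet_status),
    stringsAsFactors = FALSE)
  class(df) <- c("cohort", "data.frame")
  df
}
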