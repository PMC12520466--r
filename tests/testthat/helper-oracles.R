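# Independent closed-form oracles used to cross-check the implementation.

# OLS by explicit matrix algebra, independent of stats::lm.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  ssr <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  df <- length(x) - 2
  se_slope <- sqrt(ssr / df / sum((x - mean(x))^2))
  tstat <- beta[2] / se_slope
  list(
    slope = unname(beta[2]), intercept = unname(beta[1]),
    r_squared = 1 - ssr / sst,
    p_value = 2 * stats::pt(-abs(tstat), df)
  )
}

# Blood dose coefficient straight from its defining formula.
coefficient_oracle <- function(weight_kg, bvl_ml, tau_h) {
  (15.12 / bvl_ml + 0.0188 / weight_kg^(2 / 3)) * tau_h
}

# Convenience: small synthetic cohort run through the full pipeline.
run_synthetic_pipeline <- function(n, seed, ...) {
  cohort <- generate_cohort(cohort_config(n_patients = n, seed = seed, ...))
  blood_dosimetry(cohort$patients, cohort$administrations, cohort$readings)
}
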