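# Shared fixture builders: small seeded cohorts used across test files.

# Independent-feature expression matrix (no planted DE), unit noise.
h_noise_matrix <- function(n_features, n_samples, seed) {
  sim <- simulate_case_control(n_features,
                               n_tumor = ceiling(n_samples / 2),
                               n_normal = floor(n_samples / 2),
                               de_fraction = 0, effect_lfc = 1,
                               noise_sd = 1, seed = seed)
  sim$matrix
}

# Cohort with a planted signature on the given matrix.
h_survival_cohort <- function(matrix, genes, betas, censor_rate = 0.3,
                              seed = 1) {
  simulate_survival(matrix, genes, betas, censor_rate = censor_rate,
                    seed = seed)
}

# Direct partial log-likelihood for a single covariate without ties:
# independent oracle for cox_fit, written from the definition.
h_plik_1d <- function(beta, x, time, event) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Brute-force BH adjustment: sort, n*p/rank, cumulative minimum from the
# largest p down, monotonicity enforced. Reference for p.adjust usage.
h_bh_reference <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}
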