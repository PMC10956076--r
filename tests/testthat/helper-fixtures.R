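# Shared fixtures and independent oracles, all built in code at test time.

canonical_params <- function() nm_params(A = 3.25, a = 100, B = 22, b = 50, p = 220)

# short variant of the benchmark scenario for fast unit tests
short_scenario <- function(seed = 1, duration = 4, sigma2 = 1.3) {
  benchmark_scenario(seed = seed, duration = duration, sigma2 = sigma2)
}

# Independent stochastic-EnKF measurement update written as explicit
# per-member loops and sums; shares the perturbation draws with the
# implementation through the `draws` argument.
hand_enkf_update <- function(X, alpha, beta, R, y_obs, draws) {
  N <- ncol(X)
  H <- c(0, 1, -1, rep(0, 8))
  alpha_new <- alpha + 1 / 2
  R_eff <- R * beta / alpha_new

  m_pred <- numeric(11)
  for (i in 1:N) m_pred <- m_pred + X[, i]
  m_pred <- m_pred / N
  P_pred <- matrix(0, 11, 11)
  for (i in 1:N) P_pred <- P_pred + tcrossprod(X[, i] - m_pred)
  P_pred <- P_pred / (N - 1)

  Y <- numeric(N)
  for (i in 1:N) Y[i] <- sum(H * X[, i])
  Ybar <- sum(Y) / N
  Pyy <- sum((Y - Ybar)^2) / (N - 1) + R_eff
  Pxy <- numeric(11)
  for (i in 1:N) Pxy <- Pxy + (X[, i] - m_pred) * (Y[i] - Ybar)
  Pxy <- Pxy / (N - 1)
  K <- Pxy / Pyy

  Xn <- X
  for (i in 1:N) {
    w_i <- sqrt(R_eff) * draws[i]
    Xn[, i] <- X[, i] + K * (y_obs + w_i - Y[i])
  }
  m_new <- rowMeans(Xn)
  P_new <- P_pred - tcrossprod(K) * Pyy
  P_new <- (P_new + t(P_new)) / 2
  beta_new <- beta +
    0.5 * ((y_obs - sum(H * m_new))^2 + drop(t(H) %*% P_new %*% H)) / R
  list(members = Xn, mean = m_new, cov = P_new,
       alpha = alpha_new, beta = beta_new, R_eff = R_eff)
}

# surrogate with power spectrum ~ 1/f^chi via spectral shaping of white noise
one_over_f_noise <- function(n, fs, chi, seed = 1) {
  set.seed(seed)
  z <- fft(rnorm(n))
  f <- c(1e-12, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)  # two-sided frequency axis
  amp <- f^(-chi / 2)
  amp[1] <- 0
  Re(fft(z * amp, inverse = TRUE)) / n
}

# cohort of virtual participants with stage-dependent true mE/I means
# (deep NREM highest) plus participant noise
synthetic_cohort <- function(n_participants = 19, sd = 0.02, seed = 42) {
  set.seed(seed)
  means <- c(Awake = 0.12, S1 = 0.13, S2 = 0.15, `S3/4` = 0.18, REM = 0.125)
  tidyr::expand_grid(participant = seq_len(n_participants),
                     stage = names(means)) |>
    dplyr::mutate(mei = rnorm(dplyr::n(), means[stage], sd))
}

# simple three-stage hypnogram used by stage-average tests
toy_hypnogram <- function() {
  hypnogram(onset = seq(0, 150, by = 30), duration = rep(30, 6),
            stage = c("Awake", "S1", "S2", "S3/4", "REM", "REM"))
}

# ensemble container with sample moments, as the update step expects
ens_moments_for_test <- function(X) {
  m <- rowMeans(X)
  P <- tcrossprod(X - m) / (ncol(X) - 1)
  list(members = X, mean = m, cov = (P + t(P)) / 2)
}

.state_name_for_test <- function(i) {
  c("v0", "v1", "v2", "v3", "v4", "v5", "A", "a", "B", "b", "p")[i]
}
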