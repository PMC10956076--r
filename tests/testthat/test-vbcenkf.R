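test_that("initial ensemble respects the prior, the constraints and the seed", {
  cfg <- filter_config(n_ens = 100)
  cs <- constraint_set()

  set.seed(1); st1 <- init_filter(cfg, cs)
  set.seed(1); st2 <- init_filter(cfg, cs)
  expect_identical(st1, st2)
  expect_equal(st1$posterior$alpha, 1)
  expect_equal(st1$posterior$beta, 0.5)

  # every member inside the feasible box
  for (k in seq_along(cs$idx)) {
    comp <- st1$ensemble$members[cs$idx[k], ]
    expect_true(all(comp >= cs$lower[k] - 1e-12 & comp <= cs$upper[k] + 1e-12))
  }

  # degenerate prior: all members equal x0 (x0 feasible here, so projection
  # leaves them untouched)
  cfg0 <- filter_config(n_ens = 10, P0 = matrix(0, 11, 11))
  st0 <- init_filter(cfg0, cs)
  expect_true(all(abs(st0$ensemble$members - cfg0$x0) < 1e-5))

  expect_error(filter_config(P0 = diag(-1, 11)), "semidefinite")
})

test_that("prediction step: RK4 equivalence and parameter carry with Q = 0", {
  # single-member equivalence with the nm_model integrator
  x1 <- c(0.1, 4, 2, 0, 10, -5, 3.25, 100, 22, 50, 220)
  ens1 <- list(members = cbind(x1, x1), mean = x1, cov = matrix(0, 11, 11))
  out <- predict_step(ens1, filter_config(n_ens = 2, Q = matrix(0, 11, 11)),
                      resample = FALSE)
  oracle <- rk4_step(x1[1:6], nm_params(A = 3.25, a = 100, B = 22, b = 50, p = 220),
                     0.01)
  expect_equal(out$members[1:6, 1], oracle, tolerance = 1e-12)
  # parameter block carried unchanged under the random-walk model with Q = 0
  expect_equal(out$members[7:11, 1], x1[7:11])
})

test_that("update step follows the variational bookkeeping and the H structure", {
  cfg <- filter_config(n_ens = 3)
  cs <- constraint_set()
  set.seed(4)
  st <- init_filter(cfg, cs)
  ens <- predict_step(st$ensemble, cfg)
  upd <- vb_update_step(ens, st$posterior, y_obs = 1.0, cfg)
  # alpha goes 1 -> 1.5 on the first scalar update
  expect_equal(upd$posterior$alpha, 1.5)
  expect_gt(upd$posterior$beta, st$posterior$beta)
  # predicted observation is the v1 - v2 component of the predicted mean
  expect_equal(upd$y_pred, ens$mean[2] - ens$mean[3])

  # gamma bookkeeping over a run: alpha = alpha0 + T/2 exactly
  rec <- simulate_eeg(short_scenario(seed = 2, duration = 2))
  fit <- run_vbcenkf(rec$y_obs, filter_config(n_ens = 30, seed = 2))
  expect_equal(fit$estimates$alpha[200], 1 + 200 / 2)
  expect_true(all(fit$estimates$R_eff > 0))
})

test_that("zero-spread ensemble gives zero gain but the rate still grows", {
  cfg <- filter_config(n_ens = 2)
  x <- c(rep(0.5, 6), 3.25, 100, 22, 50, 220)
  ens <- list(members = cbind(x, x), mean = x, cov = matrix(0, 11, 11))
  post <- list(alpha = 1, beta = 0.5, R = 50)
  upd <- vb_update_step(ens, post, y_obs = 2.0, cfg, obs_draws = c(0, 0))
  expect_equal(upd$ensemble$mean, x)
  # beta increment computed by hand: alpha -> 1.5, posterior mean unchanged,
  # H x = 0, P = 0, so beta += 0.5 * (2 - 0)^2 / 50
  expect_equal(upd$posterior$beta, 0.5 + 0.5 * 4 / 50)
})

test_that("one update matches an independent hand-coded stochastic EnKF", {
  cfg <- filter_config(n_ens = 3)
  set.seed(7)
  X <- matrix(rnorm(33, sd = 2), nrow = 11) +
    c(rep(0, 6), 3.25, 100, 22, 50, 220)
  ens <- ens_moments_for_test(X)
  post <- list(alpha = 1, beta = 0.5, R = 50)
  draws <- rnorm(3)
  upd <- vb_update_step(ens, post, y_obs = 1.7, cfg, obs_draws = draws)
  ref <- hand_enkf_update(X, alpha = 1, beta = 0.5, R = 50, y_obs = 1.7, draws)
  expect_equal(upd$ensemble$members, ref$members, tolerance = 1e-10)
  expect_equal(upd$ensemble$mean, ref$mean, tolerance = 1e-10)
  expect_equal(upd$ensemble$cov, ref$cov, tolerance = 1e-10)
  expect_equal(upd$posterior$alpha, ref$alpha)
  expect_equal(upd$posterior$beta, ref$beta, tolerance = 1e-10)
  expect_equal(upd$R_eff, ref$R_eff)
})

test_that("constraint projection clamps active rows and preserves the rest", {
  cs <- constraint_set()
  x_ok <- c(rep(0, 6), 3.25, 100, 22, 50, 220)
  P <- diag(11)
  expect_identical(apply_constraints(x_ok, P, cs), x_ok)

  # identity covariance: projection reduces to componentwise clamping
  x_bad <- x_ok; x_bad[7] <- 0.2; x_bad[11] <- 400
  out <- apply_constraints(x_bad, P, cs)
  expect_equal(out[7], 1)     # A at lower bound
  expect_equal(out[11], 320)  # p at upper bound
  expect_equal(out[-c(7, 11)], x_bad[-c(7, 11)])

  # correlated covariance: active component still lands exactly on the bound
  set.seed(3)
  Arnd <- matrix(rnorm(121), 11)
  Pc <- crossprod(Arnd) + diag(0.1, 11)
  out_c <- apply_constraints(x_bad, Pc, cs)
  expect_equal(out_c[7], 1)
  expect_equal(out_c[11], 320)

  # singular D P D^T falls back to clamping
  out_s <- apply_constraints(x_bad, matrix(0, 11, 11), cs)
  expect_equal(out_s[7], 1)
  expect_equal(out_s[11], 320)
})

test_that("the filter is reproducible and keeps estimates inside the constraints", {
  rec <- simulate_eeg(short_scenario(seed = 5, duration = 2))
  cfg <- filter_config(n_ens = 40, seed = 13)
  f1 <- run_vbcenkf(rec$y_obs, cfg)
  f2 <- run_vbcenkf(rec$y_obs, cfg)
  expect_identical(f1$estimates, f2$estimates)

  # constant-zero input: parameter estimates stay inside the feasible box
  f0 <- run_vbcenkf(rep(0, 150), filter_config(n_ens = 30, seed = 1))
  cs <- constraint_set()
  for (k in seq_along(cs$idx)) {
    comp <- f0$estimates[[.state_name_for_test(cs$idx[k])]]
    expect_true(all(comp >= cs$lower[k] - 1e-9 & comp <= cs$upper[k] + 1e-9))
  }
})

test_that("tidy and glance expose the fit in standard shapes", {
  rec <- simulate_eeg(short_scenario(seed = 6, duration = 2))
  fit <- run_vbcenkf(rec$y_obs, filter_config(n_ens = 30, seed = 6))
  td <- tidy(fit)
  expect_setequal(unique(td$term),
                  c("v0", "v1", "v2", "v3", "v4", "v5", "A", "a", "B", "b", "p"))
  expect_equal(nrow(td), 200 * 11)
  expect_true(all(td$variance >= 0))
  gl <- glance(fit)
  expect_equal(gl$n_samples, 200L)
  expect_equal(gl$n_ens, 30L)
})
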