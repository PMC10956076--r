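#' Interval constraints for the augmented state
#'
#' Box constraints enforced on the parameter block of the augmented state
#' `[v0..v5, A, a, B, b, p]`. Defaults keep the filter inside the
#' physiologically meaningful regime of the neural-mass model: the inverse
#' time constants `a, b` in \[5, 200\] 1/s (synaptic time constants of
#' 5-200 ms), the background input `p` in \[120, 320\] (the alpha-like
#' limit-cycle regime), and the synaptic gains `A` in \[1, 10\] mV and `B`
#' in \[1, 50\] mV, bracketing the canonical operating values with headroom.
#'
#' @param lower,upper Named numeric vectors of bounds for a subset of the
#'   augmented-state components (default: the five parameters).
#' @return An object of class `constraint_set` with the selection indices,
#'   bounds, and the implied selection matrix `D`.
#' @export
#' @examples
#' constraint_set()
constraint_set <- function(lower = c(A = 1, a = 5, B = 1, b = 5, p = 120),
                           upper = c(A = 10, a = 200, B = 50, b = 200, p = 320)) {
  if (!identical(names(lower), names(upper))) {
    stop("`lower` and `upper` must have identical names", call. = FALSE)
  }
  idx <- match(names(lower), .state_names)
  if (anyNA(idx)) {
    stop("constraint names must be augmented-state components: ",
         paste(.state_names, collapse = ", "), call. = FALSE)
  }
  if (any(lower >= upper)) stop("need lower < upper for every row", call. = FALSE)
  D <- matrix(0, nrow = length(idx), ncol = 11)
  D[cbind(seq_along(idx), idx)] <- 1
  structure(list(names = names(lower), idx = idx, lower = unname(lower),
                 upper = unname(upper), D = D),
            class = "constraint_set")
}

#' @export
print.constraint_set <- function(x, ...) {
  cat("<constraint_set>\n")
  print(tibble::tibble(component = x$names, lower = x$lower, upper = x$upper))
  invisible(x)
}

#' Filter configuration
#'
#' Collects every tunable of the vbcEnKF. The defaults reproduce the
#' reference setting: base observation covariance `R = 50` with a gamma
#' prior `G(alpha0 = 1, beta0 = 0.5)` on the noise scaling factor (so the
#' initial effective observation covariance is `R * beta0 / alpha0 = 25`),
#' zero initial mean, and a diagonal state-noise covariance `Q` chosen by
#' preset: `"simulation"` uses `dt * 1e-2` on the six model states,
#' `"eeg"` uses `dt`; both use `1e-3` on the five parameters (random-walk
#' parameter evolution).
#'
#' @param n_ens Ensemble size (>= 2). Default 200.
#' @param dt Integration step = sampling interval in seconds. Default 0.01.
#' @param preset `"simulation"` or `"eeg"`; selects the default `Q`.
#' @param Q Optional 11x11 state-noise covariance overriding the preset.
#' @param R Base observation covariance (scalar, > 0). Default 50.
#' @param alpha0,beta0 Gamma prior (shape, rate) on the noise scale. Defaults 1, 0.5.
#' @param x0 Initial mean of the augmented state (length 11). By default
#'   the six model states start at zero and the parameter block starts at
#'   the canonical Jansen-Rit operating point
#'   `(A, a, B, b, p) = (3.25, 100, 22, 50, 220)`.
#' @param P0 11x11 initial covariance. The default spreads the six states
#'   as `N(0, 1)` and gives the parameters standard deviations
#'   `(0.25, 5, 1, 2.5, 10)` - roughly 5% relative uncertainty around the
#'   canonical operating point. Members are projected into the feasible box
#'   at initialisation.
#' @param H Observation row vector (length 11). Default selects `v1 - v2`.
#' @param guard Blow-up guard for ensemble members. Default `1e6`.
#' @param seed Optional integer seed; when set, [run_vbcenkf()] is fully
#'   reproducible.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(n_ens = 200, dt = 0.01,
                          preset = c("simulation", "eeg"),
                          Q = NULL, R = 50, alpha0 = 1, beta0 = 0.5,
                          x0 = c(rep(0, 6), 3.25, 100, 22, 50, 220),
                          P0 = diag(c(rep(1, 6), c(0.25, 5, 1, 2.5, 10)^2)),
                          H = c(0, 1, -1, rep(0, 8)),
                          guard = 1e6, seed = NULL) {
  preset <- match.arg(preset)
  if (n_ens < 2) stop("`n_ens` must be at least 2", call. = FALSE)
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (R <= 0) stop("`R` must be positive", call. = FALSE)
  if (alpha0 <= 0 || beta0 <= 0) stop("gamma prior needs alpha0, beta0 > 0", call. = FALSE)
  if (length(x0) != 11 || length(H) != 11) stop("`x0` and `H` must have length 11", call. = FALSE)
  if (is.null(Q)) {
    qv <- if (preset == "simulation") dt * 1e-2 else dt
    Q <- diag(c(rep(qv, 6), rep(1e-3, 5)))
  }
  Q <- as.matrix(Q)
  if (!isTRUE(all.equal(Q, t(Q))) || any(eigen(Q, symmetric = TRUE, only.values = TRUE)$values < -1e-12)) {
    stop("`Q` must be symmetric positive semidefinite", call. = FALSE)
  }
  P0 <- as.matrix(P0)
  if (!isTRUE(all.equal(P0, t(P0))) ||
      any(eigen(P0, symmetric = TRUE, only.values = TRUE)$values < -1e-8)) {
    stop("`P0` must be symmetric positive semidefinite", call. = FALSE)
  }
  structure(list(n_ens = as.integer(n_ens), dt = dt, preset = preset, Q = Q,
                 R = R, alpha0 = alpha0, beta0 = beta0, x0 = x0, P0 = P0,
                 H = H, guard = guard, seed = seed),
            class = "filter_config")
}

ens_moments <- function(members, Q = NULL) {
  m <- rowMeans(members)
  Xc <- members - m
  P <- tcrossprod(Xc) / (ncol(members) - 1)
  if (!is.null(Q)) P <- P + Q
  list(members = members, mean = m, cov = (P + t(P)) / 2)
}

#' Initialise the filter ensemble and noise posterior
#'
#' Samples the initial ensemble from `N(x0, P0)` and projects every member
#' into the feasible region of `constraints`. The gamma posterior over the
#' noise scale starts at `(alpha0, beta0)`.
#'
#' @param config A [filter_config()].
#' @param constraints A [constraint_set()].
#' @return A list with `ensemble` (members matrix 11 x n_ens, mean,
#'   covariance) and `posterior` (`alpha`, `beta`, `R`).
#' @export
init_filter <- function(config, constraints = constraint_set()) {
  n <- config$n_ens
  L <- tryCatch(chol(config$P0 + diag(1e-12, 11)),
                error = function(e) stop("`P0` is not positive semidefinite", call. = FALSE))
  members <- config$x0 + t(L) %*% matrix(rnorm(11 * n), nrow = 11)
  # componentwise projection into the feasible box (projection of a single
  # member equals clamping for unit-selector constraints)
  for (k in seq_along(constraints$idx)) {
    i <- constraints$idx[k]
    members[i, ] <- pmin(pmax(members[i, ], constraints$lower[k]), constraints$upper[k])
  }
  list(ensemble = ens_moments(members),
       posterior = list(alpha = config$alpha0, beta = config$beta0, R = config$R))
}

#' Prediction step of the vbcEnKF
#'
#' Propagates the ensemble through the state model: each member's six model
#' states are advanced one RK4 step using that member's own parameter
#' block, the parameter block is carried unchanged (random-walk model), and
#' an independent `N(0, Q)` perturbation is added. The predicted mean and
#' covariance are recomputed with the `1/(n_ens - 1)` normalisation plus
#' the additive `Q` term. With `resample = TRUE` (the default, and the form
#' used by [run_vbcenkf()]) the members entering the step are first drawn
#' fresh from the Gaussian `N(mean, cov)` of the incoming ensemble, so the
#' ensemble always represents the current Gaussian posterior; with
#' `resample = FALSE` the existing members are propagated as they are.
#' Members that blow up past the guard are re-sampled from the moments of
#' the surviving members (count kept in attribute `n_resampled`).
#'
#' @param ensemble Ensemble list as returned by [init_filter()].
#' @param config A [filter_config()].
#' @param resample Draw the members from `N(mean, cov)` before propagation.
#' @return The predicted ensemble (members, mean, cov).
#' @export
predict_step <- function(ensemble, config, resample = TRUE) {
  X <- ensemble$members
  n <- ncol(X)
  if (resample) {
    L0 <- chol(ensemble$cov + diag(1e-12, 11))
    X <- ensemble$mean + t(L0) %*% matrix(rnorm(11 * n), nrow = 11)
  }
  V <- rk4_matrix(X[1:6, , drop = FALSE], config$dt,
                  X[7, ], X[8, ], X[9, ], X[10, ], X[11, ])
  X[1:6, ] <- V
  if (any(config$Q != 0)) {
    Lq <- chol(config$Q + diag(1e-12, 11))
    X <- X + t(Lq) %*% matrix(rnorm(11 * n), nrow = 11)
  }

  bad <- colSums(!is.finite(X)) > 0 | apply(abs(X), 2, max) > config$guard
  n_bad <- sum(bad)
  if (n_bad > 0) {
    if (n_bad == n) stop("all ensemble members diverged", call. = FALSE)
    good <- ens_moments(X[, !bad, drop = FALSE])
    Lg <- chol(good$cov + diag(1e-10, 11))
    X[, bad] <- good$mean + t(Lg) %*% matrix(rnorm(11 * n_bad), nrow = 11)
  }
  out <- ens_moments(X, Q = config$Q)
  attr(out, "n_resampled") <- n_bad
  out
}

#' Variational Bayesian update step of the vbcEnKF
#'
#' One measurement update with online noise adaptation. The gamma shape is
#' incremented by `N/2` (scalar observation, so 1/2) and the current noise
#' scale `<eta> = alpha/beta` sets the effective observation covariance
#' `R/<eta>` used both in the innovation covariance and in the
#' perturbed-observation draws. The ensemble is updated with the stochastic
#' EnKF gain `K = P_xy / P_yy`; the posterior covariance is
#' `P - K P_yy K'`; finally the gamma rate is incremented with the
#' residual term `((y - H x)^2 + H P H') / (2 R)` evaluated at the updated
#' (posterior) mean and covariance, the variational update of the gamma
#' factor in an adaptive Kalman filter. This is what makes the effective
#' observation covariance `R/<eta>` converge to the true noise covariance
#' when the state is tracked well.
#'
#' @param ensemble Predicted ensemble (from [predict_step()]).
#' @param posterior Noise posterior list (`alpha`, `beta`, `R`).
#' @param y_obs Scalar observation.
#' @param config A [filter_config()].
#' @param obs_draws Optional length-`n_ens` vector of standard-normal draws
#'   for the observation perturbations (exposed for verification; default:
#'   drawn internally).
#' @return A list with the updated `ensemble`, `posterior`, the pre-update
#'   predicted observation `y_pred`, and the effective observation
#'   covariance `R_eff = R * beta / alpha` used in this update.
#' @export
vb_update_step <- function(ensemble, posterior, y_obs, config, obs_draws = NULL) {
  X <- ensemble$members
  n <- ncol(X)
  H <- config$H
  alpha <- posterior$alpha + 1 / 2
  eta <- alpha / posterior$beta
  R_eff <- posterior$R / eta

  Y <- drop(crossprod(H, X))          # H . X^(i)
  ybar <- mean(Y)
  dY <- Y - ybar
  x_pred <- ensemble$mean
  P_pred <- ensemble$cov
  Pyy <- sum(dY^2) / (n - 1) + R_eff
  if (!is.finite(Pyy) || Pyy <= 0) {
    stop("filter divergence: innovation covariance is not positive", call. = FALSE)
  }
  Pxy <- (X - x_pred) %*% dY / (n - 1)
  K <- Pxy / (Pyy + 1e-10)

  if (is.null(obs_draws)) obs_draws <- rnorm(n)
  w <- sqrt(R_eff) * obs_draws
  X <- X + K %*% rbind(y_obs + w - Y)
  m <- rowMeans(X)
  P <- P_pred - tcrossprod(K) * Pyy
  P <- (P + t(P)) / 2

  y_pred <- drop(crossprod(H, x_pred))
  beta <- posterior$beta +
    0.5 * ((y_obs - drop(crossprod(H, m)))^2 + drop(crossprod(H, P %*% H))) / posterior$R

  list(ensemble = list(members = X, mean = m, cov = P),
       posterior = list(alpha = alpha, beta = beta, R = posterior$R),
       y_pred = y_pred, R_eff = R_eff)
}

#' Constrain a state estimate by covariance projection
#'
#' Enforces the interval constraints on an updated estimate with the
#' oblique (covariance-weighted) projection: for bounds `d_L <= D x <= d_U`
#' the projected points are `x - P D' (D P D')^{-1} (D x - d)`, and each
#' component that violates its bound is replaced by the corresponding
#' component of the projected point (which sits exactly on the bound for a
#' unit-selector row). Components that satisfy their bounds are untouched.
#' If `D P D'` is numerically singular the method falls back to
#' componentwise clamping (the two coincide for diagonal `P`).
#'
#' @param x Augmented-state estimate (length 11).
#' @param P Its covariance (11x11, symmetric PSD).
#' @param constraints A [constraint_set()].
#' @return The constrained estimate.
#' @export
apply_constraints <- function(x, P, constraints = constraint_set()) {
  idx <- constraints$idx
  xi <- x[idx]
  v_lo <- xi < constraints$lower
  v_up <- xi > constraints$upper
  if (!any(v_lo) && !any(v_up)) return(x)

  D <- constraints$D
  DPD <- D %*% P %*% t(D)
  PDt <- P %*% t(D)
  proj <- tryCatch({
    inv <- solve(DPD)
    list(
      xL = x - drop(PDt %*% inv %*% (xi - constraints$lower)),
      xU = x - drop(PDt %*% inv %*% (xi - constraints$upper))
    )
  }, error = function(e) NULL)

  if (is.null(proj)) {
    # singular D P D': componentwise clamp
    x[idx[v_lo]] <- constraints$lower[v_lo]
    x[idx[v_up]] <- constraints$upper[v_up]
    return(x)
  }
  x[idx[v_lo]] <- proj$xL[idx[v_lo]]
  x[idx[v_up]] <- proj$xU[idx[v_up]]
  x
}

#' Fit the neural-mass model to an EEG series with the vbcEnKF
#'
#' Runs the predict / update / constrain cycle once per sample, jointly
#' estimating the six model states and the five parameters
#' `A, a, B, b, p` from a single-channel recording, and adapts the
#' observation-noise scale online. After the constraint step the ensemble
#' is re-centred on the constrained mean so that the constraints inform the
#' subsequent dynamics. The model-based E/I ratio `mE/I(t) = A/(A + B)` is
#' computed from the constrained posterior means on a sample-by-sample
#' basis.
#'
#' @param y Numeric vector: the observed EEG, sampled at `1/config$dt` Hz.
#' @param config A [filter_config()]; set `config$seed` for reproducibility.
#' @param constraints A [constraint_set()].
#' @return An object of class `vbcenkf_fit`: a list with `estimates` (a
#'   tibble with one row per sample: time, the eleven posterior means, the
#'   one-step predicted observation `y_pred`, the effective noise
#'   covariance `R_eff`, the gamma trace `alpha`, `beta`, and `mei`), the
#'   posterior variance trace `var_diag`, the configuration, and the number
#'   of re-sampled members. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @export
#' @examples
#' rec <- simulate_eeg(benchmark_scenario(seed = 7, duration = 4))
#' fit <- run_vbcenkf(rec$y_obs, filter_config(n_ens = 60, seed = 7))
#' glance(fit)
run_vbcenkf <- function(y, config = filter_config(), constraints = constraint_set()) {
  assert_finite(y, "y")
  n_t <- length(y)
  if (n_t < 1) stop("`y` must contain at least one sample", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)

  st <- init_filter(config, constraints)
  ens <- st$ensemble
  post <- st$posterior

  xhat <- matrix(NA_real_, nrow = n_t, ncol = 11)
  vdiag <- matrix(NA_real_, nrow = n_t, ncol = 11)
  y_pred <- numeric(n_t)
  r_eff <- numeric(n_t)
  a_tr <- numeric(n_t)
  b_tr <- numeric(n_t)
  n_resampled <- 0L

  for (tt in seq_len(n_t)) {
    step_ok <- tryCatch({
      ens <- predict_step(ens, config)
      n_resampled <- n_resampled + attr(ens, "n_resampled")
      upd <- vb_update_step(ens, post, y[tt], config)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(step_ok)) {
      partial <- list(estimates = build_estimates(xhat[seq_len(tt - 1), , drop = FALSE],
                                                  y_pred[seq_len(tt - 1)],
                                                  r_eff[seq_len(tt - 1)],
                                                  a_tr[seq_len(tt - 1)],
                                                  b_tr[seq_len(tt - 1)], config$dt))
      stop(errorCondition(
        sprintf("vbcEnKF diverged at sample %d: %s", tt, conditionMessage(step_ok)),
        t = tt, partial = partial, class = "eitrack_divergence"))
    }
    post <- upd$posterior
    xc <- apply_constraints(upd$ensemble$mean, upd$ensemble$cov, constraints)
    ens <- list(members = upd$ensemble$members + (xc - upd$ensemble$mean),
                mean = xc, cov = upd$ensemble$cov)

    xhat[tt, ] <- xc
    vdiag[tt, ] <- diag(upd$ensemble$cov)
    y_pred[tt] <- upd$y_pred
    r_eff[tt] <- upd$R_eff
    a_tr[tt] <- post$alpha
    b_tr[tt] <- post$beta
  }

  structure(list(
    estimates = build_estimates(xhat, y_pred, r_eff, a_tr, b_tr, config$dt),
    var_diag = vdiag,
    config = config, constraints = constraints,
    n_resampled = n_resampled, seed = config$seed
  ), class = "vbcenkf_fit")
}

build_estimates <- function(xhat, y_pred, r_eff, a_tr, b_tr, dt) {
  colnames(xhat) <- .state_names
  est <- tibble::as_tibble(xhat)
  est <- dplyr::mutate(est,
    t = dt * seq_len(nrow(xhat)),
    y_pred = y_pred, R_eff = r_eff, alpha = a_tr, beta = b_tr,
    mei = .data$A / (.data$A + .data$B),
    .before = 1
  )
  dplyr::relocate(est, "t")
}

#' @export
print.vbcenkf_fit <- function(x, ...) {
  cat(sprintf("<vbcenkf_fit>  %d samples, n_ens = %d, preset = %s\n",
              nrow(x$estimates), x$config$n_ens, x$config$preset))
  tail1 <- dplyr::slice_tail(x$estimates, n = 1)
  cat(sprintf("  final estimates: A = %.3f, B = %.3f, mE/I = %.4f, R_eff = %.3f\n",
              tail1$A, tail1$B, tail1$mei, tail1$R_eff))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-sample estimates of a vbcEnKF fit
#'
#' @param x A `vbcenkf_fit`.
#' @param ... Unused.
#' @return A long tibble with columns `t`, `term` (state or parameter
#'   name), `estimate` and `variance` (posterior ensemble variance).
#' @method tidy vbcenkf_fit
#' @export
tidy.vbcenkf_fit <- function(x, ...) {
  est <- dplyr::select(x$estimates, "t", dplyr::all_of(.state_names))
  long <- tidyr::pivot_longer(est, -"t", names_to = "term", values_to = "estimate")
  vd <- x$var_diag
  colnames(vd) <- .state_names
  vlong <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(vd), t = x$estimates$t),
    -"t", names_to = "term", values_to = "variance")
  dplyr::left_join(long, vlong, by = c("t", "term"))
}

#' One-row summary of a vbcEnKF fit
#'
#' @param x A `vbcenkf_fit`.
#' @param ... Unused.
#' @return A tibble with the sample count, ensemble size, the time-averaged
#'   effective observation covariance over the final half of the run, the
#'   final gamma parameters, the mean absolute one-step prediction error
#'   and the number of re-sampled members.
#' @method glance vbcenkf_fit
#' @export
glance.vbcenkf_fit <- function(x, ...) {
  est <- x$estimates
  tail_half <- dplyr::slice_tail(est, n = ceiling(nrow(est) / 2))
  tibble::tibble(
    n_samples = nrow(est),
    n_ens = x$config$n_ens,
    noise_cov_tail = mean(tail_half$R_eff),
    alpha_final = est$alpha[nrow(est)],
    beta_final = est$beta[nrow(est)],
    n_resampled = x$n_resampled
  )
}

#' Write a vbcEnKF fit to CSV
#'
#' @param fit A `vbcenkf_fit`.
#' @param path Output CSV path (one row per sample).
#' @return `path`, invisibly.
#' @export
write_filter_result <- function(fit, path) {
  readr::write_csv(fit$estimates, path)
  invisible(path)
}
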