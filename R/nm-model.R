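#' Jansen-Rit neural-mass model parameters
#'
#' Bundles the five free parameters of the single-column Jansen-Rit model
#' together with the fixed synaptic connectivity constants. `A` and `B` are
#' the excitatory and inhibitory synaptic gains (mV): they scale the EPSP and
#' IPSP amplitudes and carry the excitation-inhibition balance. `a` and `b`
#' are the inverse synaptic time constants (1/s), so `1000/a` is the EPSP
#' time constant in ms. `p` is the background pulse-density input (1/s);
#' for `p` roughly in 120-320 the model settles on an alpha-like limit cycle.
#'
#' @param A Excitatory synaptic gain (mV). Default 3.25.
#' @param a Inverse excitatory time constant (1/s). Default 100.
#' @param B Inhibitory synaptic gain (mV). Default 22.
#' @param b Inverse inhibitory time constant (1/s). Default 50.
#' @param p Background input pulse density (1/s). Default 220.
#' @param C1,C2,C3,C4 Synaptic connectivity constants; the canonical values
#'   `C1 = 135`, `C2 = 108`, `C3 = C4 = 33.75` are used unless overridden.
#' @return An object of class `nm_params` (a named list).
#' @export
#' @examples
#' nm_params()
nm_params <- function(A = 3.25, a = 100, B = 22, b = 50, p = 220,
                      C1 = 135, C2 = 108, C3 = 33.75, C4 = 33.75) {
  vals <- c(A = A, a = a, B = B, b = b, p = p, C1 = C1, C2 = C2, C3 = C3, C4 = C4)
  assert_finite(vals, "nm_params")
  if (A < 0 || B < 0 || a <= 0 || b <= 0) {
    stop("gains A, B must be non-negative and rate constants a, b positive",
         call. = FALSE)
  }
  structure(as.list(vals), class = "nm_params")
}

#' @export
print.nm_params <- function(x, ...) {
  cat("<nm_params>  A =", x$A, " a =", x$a, " B =", x$B, " b =", x$b,
      " p =", x$p, "\n")
  invisible(x)
}

#' Population sigmoid of the neural-mass model
#'
#' Converts an average membrane potential (mV) into a population firing rate
#' (1/s): `5 / (1 + exp(0.56 * (6 - v)))`. Strictly increasing and bounded
#' in (0, 5); saturates without overflow for extreme inputs.
#'
#' @param v Membrane potential (mV), vectorised.
#' @return Firing rate(s) in (0, 5).
#' @export
#' @examples
#' nm_sigmoid(6)  # midpoint: 2.5
nm_sigmoid <- function(v) {
  5 / (1 + exp(0.56 * (6 - v)))
}

# vectorised vector field over ensemble columns; V is 6 x n, each parameter a
# scalar or length-n vector
nm_field <- function(V, A, a, B, b, p, C1 = 135, C2 = 108, C3 = 33.75, C4 = 33.75) {
  rbind(
    V[4, ],
    V[5, ],
    V[6, ],
    A * a * nm_sigmoid(V[2, ] - V[3, ]) - 2 * a * V[4, ] - a^2 * V[1, ],
    A * a * (p + C2 * nm_sigmoid(C1 * V[1, ])) - 2 * a * V[5, ] - a^2 * V[2, ],
    B * b * C4 * nm_sigmoid(C3 * V[1, ]) - 2 * b * V[6, ] - b^2 * V[3, ]
  )
}

#' Vector field of the Jansen-Rit model
#'
#' Evaluates the six first-order differential equations of the model at a
#' given state. `state` holds the three population postsynaptic potentials
#' `v0, v1, v2` (mV) and their derivatives `v3, v4, v5` (mV/s); the model
#' output (the synthetic EEG) is `v1 - v2`.
#'
#' @param state Numeric vector of length 6: `c(v0, v1, v2, v3, v4, v5)`.
#' @param params An [nm_params()] object.
#' @return Numeric vector of length 6, the time derivative of `state`.
#' @export
nm_derivative <- function(state, params) {
  if (length(state) != 6) stop("`state` must have length 6", call. = FALSE)
  assert_finite(state, "state")
  d <- nm_field(matrix(state, nrow = 6), params$A, params$a, params$B, params$b,
                params$p, params$C1, params$C2, params$C3, params$C4)
  drop(d)
}

# one classical RK4 step of the field for a 6 x n state matrix; parameters are
# held fixed across the four substage evaluations
rk4_matrix <- function(V, dt, A, a, B, b, p, C1 = 135, C2 = 108, C3 = 33.75, C4 = 33.75) {
  k1 <- nm_field(V, A, a, B, b, p, C1, C2, C3, C4)
  k2 <- nm_field(V + dt / 2 * k1, A, a, B, b, p, C1, C2, C3, C4)
  k3 <- nm_field(V + dt / 2 * k2, A, a, B, b, p, C1, C2, C3, C4)
  k4 <- nm_field(V + dt * k3, A, a, B, b, p, C1, C2, C3, C4)
  V + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' One fourth-order Runge-Kutta step of the neural-mass model
#'
#' Advances the model state by `dt` seconds with the classical RK4 scheme.
#' All parameters, including the background input `p`, are held constant
#' across the four substage evaluations.
#'
#' @param state Numeric vector of length 6.
#' @param params An [nm_params()] object.
#' @param dt Step size in seconds (`dt = 0` returns the state unchanged).
#' @param guard Blow-up guard: an error is raised if any component of the
#'   result exceeds this magnitude. Default `1e6`.
#' @return The state after one step.
#' @export
rk4_step <- function(state, params, dt, guard = 1e6) {
  if (length(state) != 6) stop("`state` must have length 6", call. = FALSE)
  if (dt < 0) stop("`dt` must be non-negative", call. = FALSE)
  assert_finite(state, "state")
  out <- drop(rk4_matrix(matrix(state, nrow = 6), dt, params$A, params$a,
                         params$B, params$b, params$p,
                         params$C1, params$C2, params$C3, params$C4))
  if (any(!is.finite(out)) || any(abs(out) > guard)) {
    stop("numerical blow-up in RK4 step (state exceeded guard)", call. = FALSE)
  }
  out
}

#' Define a synthetic-EEG simulation scenario
#'
#' A scenario is a piecewise-constant parameter schedule for the neural-mass
#' model plus an observation-noise level. Each row of `segments` gives the
#' parameters that hold on the half-open time interval `(t_start, t_end]`;
#' within a segment the background input is redrawn every output sample from
#' `N(p_mean, p_var)` (the second argument is a variance).
#'
#' @param segments A data frame with columns `t_start`, `t_end`, `A`, `a`,
#'   `B`, `b`, `p_mean`, `p_var`; segments must tile `(0, t_end]` without
#'   gaps or overlap.
#' @param dt Sampling interval in seconds. Default 0.01 (100 Hz).
#' @param sigma2 Variance of the additive white Gaussian observation noise.
#' @param seed Integer RNG seed making the simulated record reproducible.
#' @return An object of class `nm_scenario`.
#' @seealso [benchmark_scenario()] for the canonical two-segment validation
#'   scenario, [simulate_eeg()] to generate a record.
#' @export
nm_scenario <- function(segments, dt = 0.01, sigma2 = 1.3, seed = 1) {
  segments <- tibble::as_tibble(segments)
  need <- c("t_start", "t_end", "A", "a", "B", "b", "p_mean", "p_var")
  if (!all(need %in% names(segments))) {
    stop("`segments` must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  segments <- dplyr::arrange(segments, .data$t_start)
  if (nrow(segments) == 0 || segments$t_start[1] != 0) {
    stop("segments must start at time 0", call. = FALSE)
  }
  if (nrow(segments) > 1 &&
      any(abs(segments$t_start[-1] - segments$t_end[-nrow(segments)]) > 1e-12)) {
    stop("segments must tile the simulated interval without gaps or overlap",
         call. = FALSE)
  }
  if (any(segments$t_end <= segments$t_start)) {
    stop("each segment must have t_end > t_start", call. = FALSE)
  }
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (sigma2 < 0) stop("`sigma2` must be non-negative", call. = FALSE)
  n <- round(max(segments$t_end) / dt)
  structure(
    list(segments = segments, dt = dt, n = as.integer(n),
         sigma2 = sigma2, seed = as.integer(seed)),
    class = "nm_scenario"
  )
}

#' The two-segment benchmark scenario
#'
#' The validation scenario used throughout the package: 30 s of model output
#' at 100 Hz (3000 samples) with a step change of the synaptic parameters at
#' t = 15 s. Segment 1 uses `A = 3.25`, `B = 22`, `b = 50`; segment 2 uses
#' `A = 4.25`, `B = 19`, `b = 52`; `a = 100` throughout and
#' `p ~ N(220, 22)` is redrawn each sample. White observation noise with
#' variance 1.3 is added, which puts the power signal-to-noise ratio of the
#' observed series below 5. The step raises the true model-based E/I ratio
#' `A/(A+B)` from 0.1287 to 0.1828.
#'
#' @param seed Integer RNG seed.
#' @param duration Total duration in seconds. Default 30.
#' @param sigma2 Observation-noise variance. Default 1.3.
#' @return An `nm_scenario` object.
#' @export
#' @examples
#' sc <- benchmark_scenario(seed = 1)
#' sc$n  # 3000 samples
benchmark_scenario <- function(seed = 1, duration = 30, sigma2 = 1.3) {
  half <- duration / 2
  segs <- tibble::tibble(
    t_start = c(0, half),
    t_end   = c(half, duration),
    A = c(3.25, 4.25),
    a = c(100, 100),
    B = c(22, 19),
    b = c(50, 52),
    p_mean = 220,
    p_var  = 22
  )
  nm_scenario(segs, dt = 0.01, sigma2 = sigma2, seed = seed)
}

#' Simulate a synthetic EEG record from the neural-mass model
#'
#' Integrates the model with RK4 at the scenario's sampling interval,
#' starting from the zero state. The background input `p` is redrawn once
#' per output sample and held constant across the four RK4 substages; white
#' Gaussian observation noise is added to the clean output `y = v1 - v2`.
#' Fully reproducible from the scenario seed.
#'
#' @param scenario An [nm_scenario()] object.
#' @param burn_in Number of initial seconds to drop from the returned record
#'   (default 0; the full record including the start-up transient is kept).
#' @return A tibble of class `nm_simulation` with one row per sample and
#'   columns `t`, `y_clean`, `y_obs`, `noise`, the six states `v0..v5` and
#'   the realised parameters `A, a, B, b, p`. Attributes `dt`, `sigma2`,
#'   `seed` carry the scenario settings.
#' @export
#' @examples
#' rec <- simulate_eeg(benchmark_scenario(seed = 42))
#' head(rec)
simulate_eeg <- function(scenario, burn_in = 0) {
  stopifnot(inherits(scenario, "nm_scenario"))
  n <- scenario$n
  dt <- scenario$dt
  segs <- scenario$segments
  set.seed(scenario$seed)

  # per-sample parameter schedule: sample i covers (t_{i-1}, t_i], t_i = i*dt
  t_axis <- (1:n) * dt
  seg_id <- findInterval(t_axis - dt / 2, segs$t_start)
  p_draw <- rnorm(n, mean = segs$p_mean[seg_id], sd = sqrt(segs$p_var[seg_id]))

  states <- matrix(0, nrow = n, ncol = 6)
  V <- matrix(0, nrow = 6, ncol = 1)
  for (i in 1:n) {
    s <- seg_id[i]
    V <- rk4_matrix(V, dt, segs$A[s], segs$a[s], segs$B[s], segs$b[s], p_draw[i])
    if (any(!is.finite(V)) || any(abs(V) > 1e6)) {
      stop(sprintf("numerical blow-up during simulation at sample %d", i),
           call. = FALSE)
    }
    states[i, ] <- V
  }
  y_clean <- states[, 2] - states[, 3]
  noise <- rnorm(n, 0, sqrt(scenario$sigma2))

  out <- tibble::tibble(
    t = t_axis,
    y_clean = y_clean,
    y_obs = y_clean + noise,
    noise = noise,
    v0 = states[, 1], v1 = states[, 2], v2 = states[, 3],
    v3 = states[, 4], v4 = states[, 5], v5 = states[, 6],
    A = segs$A[seg_id], a = segs$a[seg_id],
    B = segs$B[seg_id], b = segs$b[seg_id],
    p = p_draw
  )
  if (burn_in > 0) out <- dplyr::filter(out, t > burn_in)
  structure(out, dt = dt, sigma2 = scenario$sigma2, seed = scenario$seed,
            class = c("nm_simulation", class(out)))
}

#' Power signal-to-noise ratio of a simulated record
#'
#' The SNR convention used for the synthetic validation data: the ratio of
#' signal variance to noise variance, together with its base-10 logarithm.
#'
#' @param clean Clean signal series.
#' @param noise Realised noise series of the same length.
#' @return A one-row tibble with `power_ratio = var(clean)/var(noise)` and
#'   `log10_ratio = log10(power_ratio)`.
#' @export
snr_power <- function(clean, noise) {
  if (length(clean) != length(noise)) {
    stop("`clean` and `noise` must have equal length", call. = FALSE)
  }
  vn <- var(noise)
  if (!is.finite(vn) || vn <= 0) {
    stop("noise series must have positive variance", call. = FALSE)
  }
  pr <- var(clean) / vn
  tibble::tibble(power_ratio = pr, log10_ratio = log10(pr))
}

#' Write a simulated record to CSV with a JSON sidecar
#'
#' @param record An `nm_simulation` tibble.
#' @param path Output CSV path; a `<path>.json` sidecar records the scenario
#'   settings (dt, noise variance, seed).
#' @return `path`, invisibly.
#' @export
write_simulation <- function(record, path) {
  readr::write_csv(dplyr::select(record, -"noise"), path)
  side <- list(dt = attr(record, "dt"), sigma2 = attr(record, "sigma2"),
               seed = attr(record, "seed"), n = nrow(record))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
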