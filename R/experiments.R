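#' Mean absolute error between observed and predicted series
#'
#' The prediction score used throughout the validation study:
#' `mean(|y_obs - y_pred|)` between the observed EEG and the filter's
#' one-step predicted observation.
#'
#' @param y_obs,y_pred Equal-length numeric series.
#' @return A single number.
#' @export
mae <- function(y_obs, y_pred) {
  if (length(y_obs) != length(y_pred)) {
    stop("`y_obs` and `y_pred` must have equal length", call. = FALSE)
  }
  mean(abs(y_obs - y_pred))
}

#' Time-averaged estimated observation-noise covariance
#'
#' Averages the effective observation covariance `R/<eta>` over the final
#' `fraction` of a filter run. Once the filter has locked on, this is the
#' filter's estimate of the observation-noise variance of the recording.
#'
#' @param fit A `vbcenkf_fit`.
#' @param fraction Tail share of samples to average over, in (0, 1].
#'   Default 0.5 (the last half of the run).
#' @return A single number.
#' @export
noise_covariance_estimate <- function(fit, fraction = 0.5) {
  stopifnot(inherits(fit, "vbcenkf_fit"))
  if (fraction <= 0 || fraction > 1) {
    stop("`fraction` must be in (0, 1]", call. = FALSE)
  }
  r <- fit$estimates$R_eff
  mean(r[seq.int(length(r) - ceiling(length(r) * fraction) + 1, length(r))])
}

#' Full ensemble-size grid of the reference sweep design
#'
#' @return The sizes 40, 60, ..., 500 (24 values).
#' @export
sweep_sizes_full <- function() seq(40L, 500L, by = 20L)

# deterministic per-cell seed derivation, kept well below 2^31
derive_seed <- function(base_seed, i, j) {
  as.integer((as.numeric(base_seed) * 1009 + i * 99991 + j * 101) %% 2147483587)
}

#' Ensemble-size sweep on a shared synthetic record
#'
#' Repeats the filter over a grid of ensemble sizes and trial seeds on one
#' fixed synthetic record (the same data for every cell, so cells differ
#' only in the filter's Monte-Carlo seed), recording the one-step
#' prediction MAE and the estimated observation-noise covariance per cell.
#' Defaults are the desk-scale design (3 sizes x 5 trials); pass
#' `sizes = sweep_sizes_full(), n_trials = 50` for the full reference
#' design.
#'
#' @param sizes Integer vector of ensemble sizes. Default `c(40, 100, 200)`.
#' @param n_trials Trials (distinct filter seeds) per size. Default 5.
#' @param base_seed Root seed; the synthetic record and every cell seed are
#'   derived from it. Default 1.
#' @param scenario The simulation scenario; default
#'   `benchmark_scenario(seed = base_seed)`.
#' @param config Template [filter_config()]; `n_ens` and `seed` are
#'   overridden per cell.
#' @param constraints A [constraint_set()].
#' @return A tibble of class `ei_sweep` with one row per (size, trial):
#'   `n_ens`, `trial`, `seed`, `mae`, `noise_cov`, `diverged`. The shared
#'   record is attached as attribute `record`.
#' @export
#' @examples
#' \donttest{
#' sw <- ensemble_sweep(sizes = c(40, 100), n_trials = 2)
#' dplyr::summarise(dplyr::group_by(sw, n_ens), mae = median(mae))
#' }
ensemble_sweep <- function(sizes = c(40L, 100L, 200L), n_trials = 5,
                           base_seed = 1,
                           scenario = benchmark_scenario(seed = base_seed),
                           config = filter_config(),
                           constraints = constraint_set()) {
  if (n_trials < 1) stop("`n_trials` must be at least 1", call. = FALSE)
  record <- simulate_eeg(scenario)
  grid <- tidyr::expand_grid(n_ens = as.integer(sizes), trial = seq_len(n_trials))
  out <- purrr::pmap_dfr(grid, function(n_ens, trial) {
    cfg <- config
    cfg$n_ens <- n_ens
    cfg$seed <- derive_seed(base_seed, match(n_ens, sizes), trial)
    fit <- tryCatch(run_vbcenkf(record$y_obs, cfg, constraints),
                    error = function(e) NULL)
    if (is.null(fit)) {
      tibble::tibble(n_ens = n_ens, trial = trial, seed = cfg$seed,
                     mae = NA_real_, noise_cov = NA_real_, diverged = TRUE)
    } else {
      tibble::tibble(n_ens = n_ens, trial = trial, seed = cfg$seed,
                     mae = mae(record$y_obs, fit$estimates$y_pred),
                     noise_cov = noise_covariance_estimate(fit),
                     diverged = FALSE)
    }
  })
  structure(out, record = record, base_seed = base_seed,
            class = c("ei_sweep", class(out)))
}
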