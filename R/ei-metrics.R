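#' Model-based E/I ratio
#'
#' The excitation-inhibition index computed from the synaptic gains of the
#' neural-mass model: `mE/I = A / (A + B)`. Values lie strictly in (0, 1)
#' for positive gains; larger values mean excitation-dominant dynamics.
#' Scale-invariant: only the ratio of the gains matters.
#'
#' @param A Excitatory synaptic gain(s), > 0 (vectorised).
#' @param B Inhibitory synaptic gain(s), > 0.
#' @return `A / (A + B)`.
#' @export
#' @examples
#' mei_ratio(3.25, 22)   # 0.1287...
#' mei_ratio(4.25, 19)   # 0.1828...
mei_ratio <- function(A, B) {
  assert_finite(A, "A"); assert_finite(B, "B")
  if (any(A + B == 0)) stop("`A + B` must be non-zero", call. = FALSE)
  A / (A + B)
}

#' Per-sample E/I ratio series from a filter fit
#'
#' Evaluates [mei_ratio()] on the estimated gain trajectories of a
#' [run_vbcenkf()] fit, one value per processed sample.
#'
#' @param fit A `vbcenkf_fit`.
#' @return A tibble with columns `t`, `value` and `method = "mei"`.
#' @export
mei_series <- function(fit) {
  stopifnot(inherits(fit, "vbcenkf_fit"))
  tibble::tibble(t = fit$estimates$t,
                 value = mei_ratio(fit$estimates$A, fit$estimates$B),
                 method = "mei")
}

# Welch power spectral density: averaged modified periodograms over
# Hann-windowed segments
welch_psd <- function(x, fs, window_sec = 2, overlap = 0.5) {
  nseg <- round(window_sec * fs)
  if (length(x) < nseg) {
    stop("series shorter than one PSD window", call. = FALSE)
  }
  step <- max(1, round(nseg * (1 - overlap)))
  starts <- seq(1, length(x) - nseg + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nseg - 1) / (nseg - 1))
  norm <- sum(w^2) * fs
  nfreq <- floor(nseg / 2) + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(fft(seg))^2 / norm
    acc <- acc + sp[1:nfreq]
  }
  tibble::tibble(freq = (seq_len(nfreq) - 1) * fs / nseg,
                 power = acc / length(starts))
}

#' Spectral-slope E/I index (baseline method)
#'
#' The prior power-spectrum-based E/I estimate: the slope of the log-log
#' power spectral density in the gamma band, by default 30-50 Hz. The PSD
#' is a Welch estimate (2-s Hann windows, 50% overlap) and the slope is the
#' ordinary least-squares fit of `log10(power)` on `log10(frequency)` over
#' all bins whose centre lies in the closed band. A steeper (more negative)
#' slope is read as more inhibition-dominant. The band must lie within the
#' Nyquist range: a band reaching past `fs/2` is an error, not a silent
#' truncation - at 100 Hz sampling only content up to 50 Hz is observable,
#' which is precisely this estimator's limitation on such recordings.
#'
#' @param x EEG series.
#' @param fs Sampling frequency (Hz).
#' @param band Length-2 numeric, fit band in Hz. Default `c(30, 50)`.
#' @param window_sec Welch window length in seconds. Default 2.
#' @param overlap Welch window overlap fraction. Default 0.5.
#' @return The fitted slope (a single number).
#' @export
ei_slope <- function(x, fs, band = c(30, 50), window_sec = 2, overlap = 0.5) {
  if (length(band) != 2 || band[1] <= 0 || band[1] >= band[2]) {
    stop("`band` must be (lo, hi) with 0 < lo < hi", call. = FALSE)
  }
  if (band[2] > fs / 2) {
    stop(sprintf("band upper edge %.1f Hz exceeds the Nyquist frequency %.1f Hz",
                 band[2], fs / 2), call. = FALSE)
  }
  psd <- welch_psd(x, fs, window_sec, overlap)
  psd <- dplyr::filter(psd, freq >= band[1], freq <= band[2], power > 0)
  if (nrow(psd) < 3) stop("fewer than 3 PSD bins in the fit band", call. = FALSE)
  unname(stats::coef(stats::lm(log10(power) ~ log10(freq), data = psd))[2])
}

#' Windowed spectral-slope series
#'
#' Time-resolved version of [ei_slope()]: the slope is evaluated in
#' consecutive non-overlapping windows (30 s by default, the standard
#' sleep-scoring epoch length).
#'
#' @inheritParams ei_slope
#' @param win_sec Window length in seconds. Default 30.
#' @return A tibble with `t` (window centre, s), `value` (slope) and
#'   `method = "slope"`.
#' @export
ei_slope_series <- function(x, fs, band = c(30, 50), win_sec = 30,
                            window_sec = 2, overlap = 0.5) {
  if (band[2] > fs / 2) {
    stop(sprintf("band upper edge %.1f Hz exceeds the Nyquist frequency %.1f Hz",
                 band[2], fs / 2), call. = FALSE)
  }
  nwin <- round(win_sec * fs)
  if (length(x) < nwin) stop("series shorter than one window", call. = FALSE)
  starts <- seq(1, length(x) - nwin + 1, by = nwin)
  if (length(starts) == 0) stop("series shorter than one window", call. = FALSE)
  purrr::map_dfr(starts, function(s) {
    tibble::tibble(
      t = (s - 1 + nwin / 2) / fs,
      value = ei_slope(x[s:(s + nwin - 1)], fs, band, window_sec, overlap),
      method = "slope"
    )
  })
}
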