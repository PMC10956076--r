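#' Band-pass filter an EEG recording
#'
#' Zero-phase FIR band-pass used before fitting the model to sleep EEG:
#' 6000-tap Hann-window design, passband 0.6-20 Hz, applied
#' forward-backward (filtfilt) so no phase distortion is introduced. The
#' 20 Hz upper edge keeps the delta-to-beta range that carries the
#' sleep-dependent oscillations and discards muscle-artifact-prone gamma.
#'
#' The forward-backward pass is applied in the frequency domain (the series
#' is zero-padded and multiplied by the squared magnitude response of the
#' FIR), which is exact for a linear-phase FIR and avoids its group delay;
#' roughly one filter length at each end of the output carries the usual
#' filtfilt edge transient.
#'
#' @param x EEG series.
#' @param fs Sampling frequency (Hz); must exceed twice the upper edge.
#' @param low,high Passband edges in Hz. Defaults 0.6 and 20.
#' @param n_taps FIR length. Default 6000.
#' @return The filtered series (same length as `x`).
#' @export
bandpass_eeg <- function(x, fs, low = 0.6, high = 20, n_taps = 6000) {
  if (fs <= 2 * high) stop("`fs` must exceed twice the passband upper edge", call. = FALSE)
  if (length(x) <= n_taps) {
    stop(sprintf("series too short for a %d-tap zero-phase filter", n_taps),
         call. = FALSE)
  }
  h <- signal::fir1(n_taps - 1, c(low, high) / (fs / 2), type = "pass",
                    window = signal::hanning(n_taps))
  n <- length(x)
  nfft <- stats::nextn(n + 2 * n_taps, 2)
  H <- fft(c(h, rep(0, nfft - n_taps)))
  X <- fft(c(x, rep(0, nfft - n)))
  y <- Re(fft(X * Mod(H)^2, inverse = TRUE)) / nfft
  y[seq_len(n)]
}

.stage_levels <- c("Awake", "S1", "S2", "S3/4", "REM", "other")

#' Map raw sleep-stage annotation strings to the package vocabulary
#'
#' Converts the annotation labels used by public sleep EEG repositories
#' ("Sleep stage W", "Sleep stage 1", ... "Sleep stage R") and common
#' short forms to the closed vocabulary `Awake, S1, S2, S3/4, REM, other`;
#' stages 3 and 4 are merged. Movement time and unscored epochs map to
#' `other` and are dropped from stage averages.
#'
#' @param labels Character vector of raw stage labels.
#' @return Character vector over the closed vocabulary.
#' @export
map_sleep_stage <- function(labels) {
  key <- toupper(trimws(sub("^Sleep stage ", "", labels, ignore.case = TRUE)))
  out <- dplyr::case_when(
    key %in% c("W", "WAKE", "AWAKE", "0") ~ "Awake",
    key %in% c("1", "S1", "N1") ~ "S1",
    key %in% c("2", "S2", "N2") ~ "S2",
    key %in% c("3", "4", "S3", "S4", "N3", "3/4", "S3/4") ~ "S3/4",
    key %in% c("R", "REM") ~ "REM",
    TRUE ~ "other"
  )
  out
}

#' Construct a hypnogram
#'
#' An ordered, non-overlapping sequence of scored sleep epochs.
#'
#' @param onset Epoch start times (s), increasing.
#' @param duration Epoch durations (s), positive.
#' @param stage Stage labels; raw annotation strings are mapped with
#'   [map_sleep_stage()].
#' @return A tibble of class `hypnogram` with columns `onset`, `duration`,
#'   `stage` (factor over the closed vocabulary) and `end`.
#' @export
hypnogram <- function(onset, duration, stage) {
  if (length(onset) != length(duration) || length(onset) != length(stage)) {
    stop("`onset`, `duration`, `stage` must have equal length", call. = FALSE)
  }
  stage <- as.character(stage)
  if (!all(stage %in% .stage_levels)) stage <- map_sleep_stage(stage)
  h <- tibble::tibble(onset = as.numeric(onset), duration = as.numeric(duration),
                      stage = factor(stage, levels = .stage_levels))
  h <- dplyr::arrange(h, onset)
  h$end <- h$onset + h$duration
  if (any(h$duration <= 0)) stop("epoch durations must be positive", call. = FALSE)
  if (nrow(h) > 1 && any(h$onset[-1] < h$end[-nrow(h)] - 1e-9)) {
    stop("hypnogram epochs must not overlap", call. = FALSE)
  }
  structure(h, class = c("hypnogram", class(h)))
}

#' Read a hypnogram from a CSV file
#'
#' Expects columns `onset` (s), `duration` (s) and `stage` (raw or mapped
#' labels).
#'
#' @param path CSV path.
#' @return A [hypnogram()].
#' @export
read_hypnogram_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("onset", "duration", "stage")
  if (!all(need %in% names(d))) {
    stop("hypnogram CSV needs columns onset, duration, stage", call. = FALSE)
  }
  hypnogram(d$onset, d$duration, d$stage)
}

#' Sleep onset time of a hypnogram
#'
#' The start of the first scored sleep epoch (first epoch that is neither
#' `Awake` nor `other`).
#'
#' @param h A [hypnogram()].
#' @return Onset time in seconds.
#' @export
sleep_onset <- function(h) {
  i <- which(!h$stage %in% c("Awake", "other"))[1]
  if (is.na(i)) stop("hypnogram contains no sleep epochs", call. = FALSE)
  h$onset[i]
}

#' Analysis window of a sleep recording
#'
#' The evaluation window used for stage-wise E/I statistics: from 20
#' minutes before sleep onset (clamped to the start of the recording) to
#' the end of the first contiguous REM run. Recordings whose first NREM
#' period (between sleep onset and the first REM epoch) contains an awake
#' epoch are flagged for exclusion, mirroring the interrupted-sleep
#' exclusion rule; recordings without any REM episode are unusable and
#' raise an error.
#'
#' @param h A [hypnogram()].
#' @param recording_start Start time of the recording (s). Default 0.
#' @return A one-row tibble: `t_start`, `t_end`, `onset`, `excluded`
#'   (logical), `reason`.
#' @export
analysis_window <- function(h, recording_start = 0) {
  onset <- sleep_onset(h)
  rem <- which(h$stage == "REM")
  if (length(rem) == 0) {
    stop("no REM episode in hypnogram: participant unusable", call. = FALSE)
  }
  first_rem <- rem[1]
  run_end <- first_rem
  while (run_end + 1 <= nrow(h) && h$stage[run_end + 1] == "REM") run_end <- run_end + 1

  nrem_idx <- which(h$onset >= onset & h$end <= h$onset[first_rem] + 1e-9)
  awake_in_nrem <- any(h$stage[nrem_idx] == "Awake")

  tibble::tibble(
    t_start = max(onset - 1200, recording_start),
    t_end = h$end[run_end],
    onset = onset,
    excluded = awake_in_nrem,
    reason = ifelse(awake_in_nrem, "awake epoch inside first NREM period", "")
  )
}

#' Stage-wise time average of an E/I index series
#'
#' Averages a per-sample (or per-window) index over the samples of each
#' sleep stage inside the analysis window. Samples before sleep onset are
#' labelled `Awake` (the pre-onset 20-minute baseline); `other` epochs are
#' dropped. Invariant to subdividing an epoch into shorter epochs with the
#' same label.
#'
#' @param index A tibble with columns `t` (s) and `value` (e.g. from
#'   [mei_series()] or [ei_slope_series()]).
#' @param h A [hypnogram()].
#' @param window Optional one-row tibble from [analysis_window()]; default
#'   computes it from `h`.
#' @return A tibble of class `stage_summary`: `stage`, `mean_value`,
#'   `n_samples` for each stage present in the window.
#' @export
stage_average <- function(index, h, window = analysis_window(h)) {
  stopifnot(all(c("t", "value") %in% names(index)))
  d <- dplyr::filter(index, t >= window$t_start, t <= window$t_end)
  if (nrow(d) == 0) stop("index series does not cover the analysis window", call. = FALSE)
  ep <- findInterval(d$t, h$onset)
  stage <- as.character(h$stage[pmax(ep, 1)])
  stage[ep == 0 | d$t > h$end[pmax(ep, 1)]] <- NA
  stage[d$t < window$onset] <- "Awake"
  keep <- !is.na(stage) & stage != "other"
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(stage = stage[keep], value = d$value[keep]), stage),
    mean_value = mean(value), n_samples = dplyr::n(), .groups = "drop"
  )
  out$stage <- factor(out$stage, levels = .stage_levels)
  out <- dplyr::arrange(out, stage)
  structure(out, class = c("stage_summary", class(out)))
}

rank_stats <- function(x, g) {
  r <- rank(x)
  N <- length(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties)
  list(r = r, N = N, tie_term = tie_term,
       mean_ranks = tapply(r, g, mean), n = tapply(r, g, length))
}

#' Kruskal-Wallis test with rank eta-squared effect size
#'
#' Tie-corrected Kruskal-Wallis rank test across groups, returning the H
#' statistic, its chi-squared p-value and the rank-based effect size
#' `eta^2_H = (H - k + 1) / (n - k)` for `k` groups and `n` total
#' observations.
#'
#' @param data A data frame.
#' @param value Column with the response (tidy-eval).
#' @param group Column with the grouping factor (tidy-eval).
#' @return A one-row tibble: `H`, `df`, `p_value`, `eta_squared_H`, `n`, `k`.
#' @export
#' @examples
#' d <- data.frame(v = c(1, 2, 3, 10, 11, 12), g = rep(c("x", "y"), each = 3))
#' kruskal_wallis(d, v, g)
kruskal_wallis <- function(data, value, group) {
  x <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  g <- droplevels(g)
  if (nlevels(g) < 2) stop("need at least 2 non-empty groups", call. = FALSE)
  s <- rank_stats(x, g)
  k <- nlevels(g)
  corr <- 1 - s$tie_term / (s$N^3 - s$N)
  if (corr <= 0) {
    H <- 0
  } else {
    H <- (12 / (s$N * (s$N + 1)) * sum(s$n * s$mean_ranks^2) - 3 * (s$N + 1)) / corr
  }
  p <- pchisq(H, df = k - 1, lower.tail = FALSE)
  tibble::tibble(
    H = H, df = k - 1, p_value = p,
    eta_squared_H = (H - k + 1) / (s$N - k),
    n = s$N, k = k
  )
}

#' Dunn's multiple-comparison test with pairwise effect sizes
#'
#' Two-tailed Dunn z tests on the pooled ranks for every pair of groups,
#' with tie correction, multiplicity correction of the p-values (Bonferroni
#' over all `k(k-1)/2` pairs by default) and the pairwise effect size
#' `phi^2 = z^2 / (n_i + n_j)` (Cramer's phi squared for a z-based
#' comparison).
#'
#' @inheritParams kruskal_wallis
#' @param p_adjust Correction method passed to [stats::p.adjust()].
#'   Default `"bonferroni"`.
#' @return A tibble with one row per pair: `group1`, `group2`, `z`,
#'   `p_value`, `p_adjusted`, `phi_squared`, `n1`, `n2`.
#' @export
dunn_test <- function(data, value, group, p_adjust = "bonferroni") {
  x <- dplyr::pull(data, {{ value }})
  g <- droplevels(factor(dplyr::pull(data, {{ group }})))
  if (nlevels(g) < 2) stop("need at least 2 non-empty groups", call. = FALSE)
  s <- rank_stats(x, g)
  lev <- levels(g)
  sigma2 <- s$N * (s$N + 1) / 12 - s$tie_term / (12 * (s$N - 1))
  pairs <- utils::combn(lev, 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt(sigma2 * (1 / s$n[[i1]] + 1 / s$n[[i2]]))
    z <- if (se > 0) (s$mean_ranks[[i1]] - s$mean_ranks[[i2]]) / se else 0
    tibble::tibble(
      group1 = i1, group2 = i2, z = z,
      p_value = 2 * pnorm(-abs(z)),
      phi_squared = z^2 / (s$n[[i1]] + s$n[[i2]]),
      n1 = s$n[[i1]], n2 = s$n[[i2]]
    )
  })
  out$p_adjusted <- stats::p.adjust(out$p_value, method = p_adjust)
  dplyr::relocate(out, "p_adjusted", .after = "p_value")
}

#' Stage-wise E/I statistics for a cohort
#'
#' Convenience wrapper running [kruskal_wallis()] and [dunn_test()] on a
#' cohort table of per-participant, per-stage time-averaged index values.
#'
#' @param data A data frame with one row per participant x stage.
#' @param value Column with the time-averaged index (tidy-eval).
#' @param stage Column with the sleep stage (tidy-eval).
#' @return A list with elements `kruskal` and `dunn`.
#' @export
stage_statistics <- function(data, value, stage) {
  list(kruskal = kruskal_wallis(data, {{ value }}, {{ stage }}),
       dunn = dunn_test(data, {{ value }}, {{ stage }}))
}
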