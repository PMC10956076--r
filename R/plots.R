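#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated record
#'
#' Clean and observed synthetic EEG over time.
#'
#' @param object An `nm_simulation` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot nm_simulation
#' @export
autoplot.nm_simulation <- function(object, ...) {
  d <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "t", "y_obs", "y_clean"),
    -"t", names_to = "series", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(t, value, colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "amplitude (mV)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a vbcEnKF fit
#'
#' @param object A `vbcenkf_fit`.
#' @param which `"parameters"` (the five parameter trajectories),
#'   `"mei"` (the model-based E/I ratio), or `"noise"` (the effective
#'   observation covariance trace).
#' @param truth Optional tibble with columns `t` plus any of
#'   `A, a, B, b, p` to overlay (e.g. a simulation record).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot vbcenkf_fit
#' @export
autoplot.vbcenkf_fit <- function(object, which = c("parameters", "mei", "noise"),
                                 truth = NULL, ...) {
  which <- match.arg(which)
  est <- object$estimates
  if (which == "parameters") {
    d <- tidyr::pivot_longer(
      dplyr::select(est, "t", "A", "a", "B", "b", "p"),
      -"t", names_to = "term", values_to = "estimate")
    gg <- ggplot2::ggplot(d, ggplot2::aes(t, estimate)) +
      ggplot2::geom_line(colour = "steelblue") +
      ggplot2::facet_wrap(~term, scales = "free_y") +
      ggplot2::labs(x = "time (s)", y = "estimate") +
      ggplot2::theme_minimal()
    if (!is.null(truth)) {
      dtruth <- tidyr::pivot_longer(
        dplyr::select(tibble::as_tibble(truth),
                      dplyr::any_of(c("t", "A", "a", "B", "b", "p"))),
        -"t", names_to = "term", values_to = "estimate")
      gg <- gg + ggplot2::geom_line(data = dtruth, colour = "black",
                                    linetype = "dashed")
    }
    gg
  } else if (which == "mei") {
    ggplot2::ggplot(est, ggplot2::aes(t, mei)) +
      ggplot2::geom_line(colour = "firebrick") +
      ggplot2::labs(x = "time (s)", y = "mE/I ratio") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(est, ggplot2::aes(t, .data$R_eff)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time (s)", y = "effective observation covariance") +
      ggplot2::theme_minimal()
  }
}

#' Plot an ensemble-size sweep
#'
#' MAE and estimated noise covariance against ensemble size.
#'
#' @param object An `ei_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ei_sweep
#' @export
autoplot.ei_sweep <- function(object, ...) {
  d <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "n_ens", "mae", "noise_cov"),
    -"n_ens", names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(factor(n_ens), value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "ensemble size", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a stage summary
#'
#' @param object A `stage_summary` tibble (or a cohort of them bound
#'   together).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot stage_summary
#' @export
autoplot.stage_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(stage, .data$mean_value)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "sleep stage", y = "time-averaged index") +
    ggplot2::theme_minimal()
}
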