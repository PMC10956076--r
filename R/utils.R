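#' @importFrom rlang %||% .data
#' @importFrom stats var rnorm pchisq pnorm sd
NULL

# state vector layout of the augmented system: six membrane-potential states
# followed by the five free model parameters
.state_names <- c("v0", "v1", "v2", "v3", "v4", "v5", "A", "a", "B", "b", "p")
.param_idx <- 7:11

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop(sprintf("`%s` must be finite (got non-finite values)", what), call. = FALSE)
  }
  invisible(x)
}

utils::globalVariables(c(
  "t", "term", "estimate", "truth", "value", "stage", "n_ens", "mae",
  "noise_cov", "y_clean", "y_obs", "A", "B", "mei", "y_pred", "freq", "power"
))
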