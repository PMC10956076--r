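# eitrack

Sample-by-sample tracking of the cortical excitation–inhibition (E/I)
balance from single-channel EEG.

EEG cannot show synaptic gains directly, and the established in-vivo
probes of E/I balance (MRS, TMS-evoked potentials) resolve it only on a
scale of minutes. `eitrack` takes a different route: it assimilates the
recording into a generative Jansen–Rit neural-mass model with a
**variational Bayesian noise-adaptive constrained ensemble Kalman filter
(vbcEnKF)**, jointly estimating the six model states and the five
physiological parameters `A, a, B, b, p` at every sample while

* adapting the observation-noise scale online through a gamma posterior
  on a noise scaling factor (`y_t = H x_t + w_t`,
  `w_t ~ N(0, eta^-1 R)`, `eta ~ G(alpha, beta)`), and
* keeping the parameters inside physiological interval constraints by
  covariance-weighted projection
  (`a, b` in [5, 200] 1/s, `p` in [120, 320], `A` in [1, 10],
  `B` in [1, 50]).

The model-based E/I index is the gain ratio

```
mE/I(t) = A(t) / (A(t) + B(t))
```

computed per sample from the filtered excitatory gain `A` and inhibitory
gain `B`. The package also ships the synthetic-EEG generator used for
validation, an ensemble-size benchmark study, the prior spectral
baseline (the 30–50 Hz log-log PSD slope), and a sleep-stage statistics
pipeline (Kruskal–Wallis with rank eta-squared, Dunn tests with
Bonferroni correction and pairwise phi-squared effect sizes).

## Worked example

Simulate the two-segment benchmark (30 s at 100 Hz; `A: 3.25 → 4.25`,
`B: 22 → 19`, `b: 50 → 52` at t = 15 s; `p ~ N(220, 22)` per sample;
observation-noise variance 1.3) and fit it:

```r
library(eitrack)
library(dplyr)

rec <- simulate_eeg(benchmark_scenario(seed = 1))
snr_power(rec$y_clean, rec$noise)
#> # A tibble: 1 × 2
#>   power_ratio log10_ratio
#>         <dbl>       <dbl>
#> 1        4.88       0.688

fit <- run_vbcenkf(rec$y_obs, filter_config(n_ens = 200, seed = 1))
glance(fit)
#> # A tibble: 1 × 6
#>   n_samples n_ens noise_cov_tail alpha_final beta_final n_resampled
#>       <int> <int>          <dbl>       <dbl>      <dbl>       <int>
#> 1      3000   200           1.45        1501       41.2           0

fit$estimates |>
  filter((t > 8 & t <= 15) | (t > 23 & t <= 30)) |>
  group_by(segment = ifelse(t <= 15, "before step", "after step")) |>
  summarise(A = mean(A), B = mean(B), mei = mean(mei))
#> # A tibble: 2 × 4
#>   segment         A     B   mei
#>   <chr>       <dbl> <dbl> <dbl>
#> 1 after step   4.75  17.8 0.211
#> 2 before step  3.50  20.5 0.146
```

Reading the numbers: the observed record's power SNR is 4.88 (the
scenario is designed to sit below 5, i.e. heavily noise-distorted); the
filter's time-averaged effective observation covariance over the second
half of the run is 1.45, close to the true noise variance 1.3; the
window-averaged gain estimates bracket the true values (A: 3.25 then
4.25; B: 22 then 19) within ~12%, and the mE/I mean rises across the
step in the direction of the true change (0.1287 → 0.1828).
`autoplot(fit, "parameters", truth = rec)` overlays the estimated and
true parameter trajectories; `tidy(fit)` returns them as a long tibble.

The ensemble-size study and the spectral baseline:

```r
sw <- ensemble_sweep(sizes = c(40, 100, 200), n_trials = 5, base_seed = 1)
sw |> group_by(n_ens) |> summarise(mae = median(mae))    # decreases with size

ei_slope(rec$y_obs, fs = 100, band = c(30, 50))          # the prior method
```

A command-line front end wrapping the same functions is in
`inst/cli/eitrack.R` (subcommands `simulate`, `fit`, `sweep`, `ei`,
`sleep`; every run writes a JSON manifest with config, seed and input
checksums).

## Documentation

The methods vignette (`vignettes/tracking-ei-balance.Rmd`) describes the
model, the filter (including the variational noise update and the
constraint projection), the defaults and why they were chosen, the
synthetic benchmark, and known limitations.
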