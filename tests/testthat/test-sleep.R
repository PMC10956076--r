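test_that("band-pass keeps the passband and suppresses out-of-band tones", {
  fs <- 100
  t <- seq(0, 250, by = 1 / fs)
  mid <- 10000:15000  # away from filtfilt edge transients

  in_band <- sin(2 * pi * 10 * t)
  out10 <- bandpass_eeg(in_band, fs)
  expect_lt(abs(sd(out10[mid]) / sd(in_band[mid]) - 1), 0.01)

  slow <- sin(2 * pi * 0.1 * t)
  fast <- sin(2 * pi * 30 * t)
  expect_lt(sd(bandpass_eeg(slow, fs)[mid]) / sd(slow[mid]), 0.1)  # > 20 dB down
  expect_lt(sd(bandpass_eeg(fast, fs)[mid]) / sd(fast[mid]), 0.1)

  expect_equal(max(abs(bandpass_eeg(rep(0, 25001), fs))), 0)
  expect_error(bandpass_eeg(rnorm(1000), fs), "too short")

  # near-idempotence in the passband
  twice <- bandpass_eeg(out10, fs)
  expect_lt(abs(sd(twice[mid]) / sd(out10[mid]) - 1), 0.02)
})

test_that("stage vocabulary mapping covers the public annotation strings", {
  expect_equal(
    map_sleep_stage(c("Sleep stage W", "Sleep stage 1", "Sleep stage 2",
                      "Sleep stage 3", "Sleep stage 4", "Sleep stage R",
                      "Movement time", "Sleep stage ?")),
    c("Awake", "S1", "S2", "S3/4", "S3/4", "REM", "other", "other")
  )
})

test_that("hypnogram constructor validates ordering and overlap", {
  h <- toy_hypnogram()
  expect_s3_class(h, "hypnogram")
  expect_equal(sleep_onset(h), 30)
  expect_error(hypnogram(c(0, 10), c(30, 30), c("Awake", "S1")), "overlap")
  expect_error(hypnogram(0, -5, "S1"), "positive")
})

test_that("analysis window follows the onset/REM rule with clamping and exclusions", {
  # onset at 3600 s, first REM run 7200-7800 s
  h <- hypnogram(
    onset = c(0, 3600, 5400, 7200, 7500, 7800),
    duration = c(3600, 1800, 1800, 300, 300, 600),
    stage = c("Awake", "S1", "S2", "REM", "REM", "S2")
  )
  w <- analysis_window(h)
  expect_equal(w$t_start, 2400)
  expect_equal(w$t_end, 7800)
  expect_false(w$excluded)

  # onset earlier than 20 min into the recording: clamp to 0
  h2 <- hypnogram(c(0, 600, 1200), c(600, 600, 600), c("Awake", "S2", "REM"))
  expect_equal(analysis_window(h2)$t_start, 0)

  # awake epoch inside the first NREM period: flagged
  h3 <- hypnogram(c(0, 600, 1200, 1800), c(600, 600, 600, 600),
                  c("S1", "Awake", "S2", "REM"))
  expect_true(analysis_window(h3)$excluded)

  # no REM: unusable
  h4 <- hypnogram(c(0, 600), c(600, 600), c("Awake", "S2"))
  expect_error(analysis_window(h4), "REM")
})

test_that("stage averages recover construction and survive epoch subdivision", {
  h <- toy_hypnogram()
  tt <- seq(0.5, 179.5, by = 1)

  # constant index: every stage mean equals the constant
  s_const <- stage_average(tibble::tibble(t = tt, value = 0.5), h)
  expect_true(all(abs(s_const$mean_value - 0.5) < 1e-12))

  # indicator of REM: REM mean 1, others 0
  rem <- as.numeric(tt >= 120)
  s_rem <- stage_average(tibble::tibble(t = tt, value = rem), h)
  expect_equal(s_rem$mean_value[s_rem$stage == "REM"], 1)
  expect_true(all(s_rem$mean_value[s_rem$stage != "REM"] == 0))

  # stage-dependent means are recovered exactly
  truth <- c(Awake = 0.10, S1 = 0.12, S2 = 0.15, `S3/4` = 0.2, REM = 0.13)
  stage_of_t <- as.character(h$stage[findInterval(tt, h$onset)])
  s_known <- stage_average(tibble::tibble(t = tt, value = truth[stage_of_t]), h)
  expect_equal(s_known$mean_value, unname(truth[as.character(s_known$stage)]))

  # subdividing epochs (same labels) leaves the means unchanged
  h_split <- hypnogram(onset = seq(0, 165, by = 15), duration = rep(15, 12),
                       stage = rep(as.character(h$stage), each = 2))
  s_split <- stage_average(tibble::tibble(t = tt, value = truth[stage_of_t]),
                           h_split)
  expect_equal(s_split$mean_value, s_known$mean_value)
})

test_that("pre-onset samples are counted as the awake baseline", {
  h <- hypnogram(c(0, 60, 120), c(60, 60, 60), c("S1", "S2", "REM"))
  # onset is 0 here; shift sleep to start at 60 instead
  h2 <- hypnogram(c(0, 60, 120), c(60, 60, 60), c("Awake", "S2", "REM"))
  tt <- seq(0.5, 179.5, by = 1)
  idx <- tibble::tibble(t = tt, value = as.numeric(tt < 60))
  s <- stage_average(idx, h2)
  expect_equal(s$mean_value[s$stage == "Awake"], 1)
  expect_true(all(s$mean_value[s$stage != "Awake"] == 0))
})

test_that("Kruskal-Wallis matches hand-computed ranks and the reference implementation", {
  d <- data.frame(v = c(1, 2, 3, 10, 11, 12, 20, 21, 22),
                  g = rep(c("a", "b", "c"), each = 3))
  kw <- kruskal_wallis(d, v, g)
  expect_equal(kw$H, 7.2)  # 12/(9*10) * (36 + 225 + 576)/3 - 30
  expect_equal(kw$df, 2)

  # identical groups: H ~ 0
  d0 <- data.frame(v = rep(c(5, 6, 7), 3), g = rep(c("a", "b", "c"), each = 3))
  expect_lt(kruskal_wallis(d0, v, g)$H, 1e-10)

  # cross-check against stats::kruskal.test on random data with ties
  set.seed(21)
  for (i in 1:5) {
    dr <- data.frame(v = sample(round(rnorm(40), 1)),
                     g = sample(rep(letters[1:4], 10)))
    ref <- stats::kruskal.test(v ~ g, data = dr)
    kwr <- kruskal_wallis(dr, v, g)
    expect_equal(kwr$H, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(kwr$p_value, ref$p.value, tolerance = 1e-10)
  }

  # invariance under strictly monotone transforms
  dr <- data.frame(v = rexp(30), g = rep(c("a", "b", "c"), 10))
  expect_equal(kruskal_wallis(dr, v, g)$H,
               kruskal_wallis(dplyr::mutate(dr, v = log(v)), v, g)$H)
})

test_that("rank eta-squared follows its defining formula", {
  # (H - k + 1) / (n - k) at the reference values H = 32.1325, k = 5, n = 95
  eta2 <- (32.1325 - 5 + 1) / (95 - 5)
  expect_equal(round(eta2, 4), 0.3126)
  d <- synthetic_cohort()
  kw <- kruskal_wallis(d, mei, stage)
  expect_equal(kw$eta_squared_H, (kw$H - kw$k + 1) / (kw$n - kw$k))
})

test_that("Dunn test agrees with the rank-sum identity and behaves on degenerate input", {
  # for k = 2 groups, the Dunn z satisfies z^2 = Kruskal-Wallis H
  set.seed(31)
  for (i in 1:5) {
    d2 <- data.frame(v = c(rnorm(8), rnorm(10, 1)),
                     g = rep(c("a", "b"), c(8, 10)))
    z <- dunn_test(d2, v, g)$z
    H <- unname(stats::kruskal.test(v ~ g, data = d2)$statistic)
    expect_equal(z^2, H, tolerance = 1e-8)
  }
  # with ties
  d2t <- data.frame(v = c(1, 1, 2, 3, 3, 3, 4, 5), g = rep(c("a", "b"), 4))
  expect_equal(dunn_test(d2t, v, g)$z^2,
               unname(stats::kruskal.test(v ~ g, data = d2t)$statistic),
               tolerance = 1e-8)

  # identical groups: all adjusted p values 1
  d0 <- data.frame(v = rep(c(5, 6, 7), 3), g = rep(c("a", "b", "c"), each = 3))
  expect_true(all(dunn_test(d0, v, g)$p_adjusted == 1))

  # the extreme pair has the largest |z|
  d3 <- data.frame(v = c(1:5, 11:15, 21:25), g = rep(c("a", "b", "c"), each = 5))
  dt3 <- dunn_test(d3, v, g)
  extreme <- dt3$group1 == "a" & dt3$group2 == "c"
  expect_equal(max(abs(dt3$z)), abs(dt3$z[extreme]))
  # effect size convention
  expect_equal(dt3$phi_squared, dt3$z^2 / (dt3$n1 + dt3$n2))
})

test_that("a stage-structured cohort yields the expected inference pattern", {
  d <- synthetic_cohort()
  st <- stage_statistics(d, mei, stage)
  expect_lt(st$kruskal$p_value, 0.01)
  deep_vs_wake <- st$dunn$p_adjusted[
    (st$dunn$group1 == "S3/4" & st$dunn$group2 == "Awake") |
    (st$dunn$group1 == "Awake" & st$dunn$group2 == "S3/4")]
  expect_lt(deep_vs_wake, 0.01)
})
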