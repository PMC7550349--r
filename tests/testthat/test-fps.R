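test_that("EMG preprocessing attenuates out-of-band input and preserves in-band rectified level", {
  fs <- 2000
  t <- seq(0, 10, by = 1 / fs)
  expect_equal(preprocess_emg(numeric(5000), fs), numeric(5000))
  # 10 Hz lies below the 28-500 Hz band
  low <- sin(2 * pi * 10 * t)
  out_low <- preprocess_emg(low, fs)
  expect_lt(sqrt(mean(out_low^2)) / sqrt(mean(low^2)), 0.05)
  # 100 Hz is in-band; rectified mean of a sine is 2A/pi
  amp <- 0.8
  mid <- amp * sin(2 * pi * 100 * t)
  out_mid <- preprocess_emg(mid, fs)
  core <- out_mid[2000:18000]  # avoid edges
  expect_equal(mean(core), 2 * amp / pi, tolerance = 0.1)
  expect_error(preprocess_emg(numeric(100), fs = 800), "cannot represent")
})

test_that("startle scoring floors at zero and matches the brute-force window oracle", {
  fs <- 2000
  par <- fps_params()
  expect_equal(score_startle(rep(0.3, 4000), fs, probe_onset = 1), 0)
  # a baseline bump larger than anything in the peak window scores 0
  x <- numeric(4000)
  x[idx <- 1901:2000] <- 0.5           # inside [-100, 0) ms before probe at 1 s
  x[2100:2150] <- 0.2                  # smaller burst inside [20, 120) ms
  expect_equal(score_startle(x, fs, probe_onset = 1), 0)
  # synthetic burst at 35 ms latency
  burst <- numeric(8000)
  tt <- seq_len(200)
  burst[2000 + 70 + tt] <- 0.4 * sin(pi * tt / 200)^2
  sc <- score_startle(burst, fs, probe_onset = 1)
  expect_equal(sc, 0.4, tolerance = 0.05)
  oracle <- oracle_window_score(burst, fs, 1, par$peak_window[1],
                                par$peak_window[2], 0.1)
  expect_equal(sc, max(0, oracle), tolerance = 1e-12)
  expect_error(score_startle(burst, fs, probe_onset = 3.999), "extends past")
})

test_that("T-scores have exact mean 50 and sd 10, and handle degenerate input", {
  expect_equal(tscore_normalize(c(0, 10)), c(50 - 10 / sqrt(2), 50 + 10 / sqrt(2)))
  expect_equal(tscore_normalize(c(0, 10)), c(42.92893, 57.07107),
               tolerance = 1e-6)
  expect_warning(out <- tscore_normalize(rep(3, 8)), "zero variance")
  expect_equal(out, rep(50, 8))
  for (seed in 1:5) {
    set.seed(seed)
    x <- rlnorm(40)
    ts <- tscore_normalize(x)
    expect_equal(mean(ts), 50, tolerance = 1e-9)
    expect_equal(sd(ts), 10, tolerance = 1e-9)
  }
})

test_that("T-scored startle magnitudes are invariant to EMG gain", {
  par <- synth_params()
  cfg <- design_config(n_cs_plus_de = 4, n_cs_minus_de = 4)
  tl <- build_timeline(cfg, "DE", seed = 14)
  emg <- render_emg(tl, par, aware = TRUE, seed = 15)
  score_t <- function(x) {
    sm <- preprocess_emg(x, par$fs)
    tscore_normalize(score_fps_trials(sm, par$fs, tl)$raw)
  }
  base <- score_t(emg)
  for (k in c(0.2, 7.5)) expect_equal(score_t(k * emg), base, tolerance = 1e-8)
})

test_that("the whole-experiment non-zero rule flips exclusion at exactly 6", {
  mk <- function(n_nonzero) {
    data.frame(trial_index = 1:36, phase = rep(c("OFL", "DE"), each = 18),
               condition = rep(c("obs_fix", "dir_fix"), each = 18),
               probe_onset = seq(5, 360, by = 10),
               raw = c(rep(0.2, n_nonzero), rep(0, 36 - n_nonzero)),
               baseline_rms = 0.01, stringsAsFactors = FALSE)
  }
  s5 <- summarize_fps_subject(mk(5))
  expect_true(s5$excluded)
  expect_identical(s5$exclusion_reason, "too_few_nonzero")
  s6 <- summarize_fps_subject(mk(6))
  expect_false(s6$excluded)
  expect_identical(s6$exclusion_reason, "none")
})

test_that("condition means of T-scores match an independent oracle", {
  set.seed(3)
  trials <- data.frame(trial_index = 1:54,
                       phase = rep(c("OFL", "DE"), c(36, 18)),
                       condition = sample(c("obs_CS_PLUS", "obs_fix", "dir_CS_PLUS",
                                            "dir_fix"), 54, replace = TRUE),
                       probe_onset = seq(5, 540, by = 10),
                       raw = rlnorm(54, sdlog = 0.4) * 0.1,
                       baseline_rms = 0.01, stringsAsFactors = FALSE)
  s <- summarize_fps_subject(trials)
  tsc <- 50 + 10 * (trials$raw - mean(trials$raw)) / sd(trials$raw)
  for (cond in names(s$condition_means))
    expect_equal(unname(s$condition_means[[cond]]),
                 sum(tsc[trials$condition == cond]) /
                   sum(trials$condition == cond),
                 tolerance = 1e-12)
})

test_that("noisy-recording flag triggers on elevated baseline RMS", {
  rms <- c(replicate(9, rep(0.01, 20), simplify = FALSE),
           list(c(rep(0.2, 8), rep(0.01, 12))))  # 40% of trials 20x the median
  flags <- flag_noisy_fps(rms)
  expect_identical(flags, c(rep(FALSE, 9), TRUE))
})
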