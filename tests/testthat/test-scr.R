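test_that("decomposition of a constant signal is all tonic", {
  for (method in c("convex_sparse", "highpass_baseline")) {
    dec <- decompose_eda(rep(4.2, 40000), fs = 2000, method = method)
    expect_lt(max(abs(dec$phasic)), 1e-3)
    expect_equal(dec$tonic, rep(4.2, 40000), tolerance = 1e-6)
    expect_equal(dec$tonic + dec$phasic + dec$residual, rep(4.2, 40000),
                 tolerance = 1e-9)
  }
  expect_error(decompose_eda(c(1, NA, 3), 2000), "non-finite")
})

test_that("a known response on a drifting baseline is recovered within 10%", {
  fs <- 2000
  t <- seq(0, 90, by = 1 / fs)
  eda <- 5 + 0.02 * t / 60 + kernel_trace(0.5, 30, dur = 90, fs = fs)
  dec <- decompose_eda(eda, fs)
  expect_equal(max(dec$phasic), 0.5, tolerance = 0.1)
  expect_gte(min(dec$phasic), -1e-6)
  expect_equal(dec$tonic + dec$phasic + dec$residual, eda, tolerance = 1e-9)
  # decomposing the recovered tonic again yields a near-zero phasic component
  dec2 <- decompose_eda(dec$tonic, fs)
  expect_lt(max(dec2$phasic), 0.01)
})

test_that("trial scoring implements windowed peak minus pre-stimulus baseline", {
  fs <- 2000
  expect_equal(score_scr_trial(numeric(20000), fs, onset = 3), 0)
  # peak - baseline of exactly 0.19 is floored to no-response
  x <- c(rep(0.10, 3 * fs), rep(0.29, 2 * fs), rep(0.10, 5 * fs))
  expect_equal(score_scr_trial(x, fs, onset = 3), 0)
  x2 <- c(rep(0.10, 3 * fs), rep(0.31, 2 * fs), rep(0.10, 5 * fs))
  expect_equal(score_scr_trial(x2, fs, onset = 3), 0.21)
  expect_error(score_scr_trial(numeric(1000), fs, onset = 3), "extends past")
})

test_that("scoring equals the brute-force oracle and recovers injected amplitude", {
  fs <- 2000
  par <- scr_params()
  x <- kernel_trace(0.5, 11.5, dur = 30, fs = fs)  # event 1.5 s after onset 10
  amp <- score_scr_trial(x, fs, onset = 10)
  expect_equal(amp, 0.5, tolerance = 1e-6)
  oracle <- oracle_window_score(x, fs, 10, par$window_start, par$window_end,
                                par$baseline_span)
  expect_equal(amp, oracle, tolerance = 1e-12)
  # translation invariance: adding a constant leaves amplitudes unchanged
  expect_equal(score_scr_trial(x + 3.7, fs, onset = 10), amp, tolerance = 1e-9)
})

test_that("US scoring drops probe-contaminated trials and stays balanced", {
  tl <- build_timeline(design_config(), "OFL", seed = 55)
  phasic <- numeric(ceiling(timeline_duration(tl) * 2000))
  us <- score_us_trials(phasic, 2000, tl)
  tr <- tl$trials[tl$trials$cs_type == "CS_PLUS", ]
  expect_identical(us$scoreable,
                   is.na(tr$probe_onset) & is.na(tr$iti_probe_onset))
  expect_true(all(!us$scoreable[!is.na(tr$probe_onset)]))
  expect_true(all(!us$scoreable[!is.na(tr$iti_probe_onset)]))
  expect_true(all(is.na(us$raw[!us$scoreable])))
  expect_equal(sum(us$scoreable & us$condition == "obs_US"),
               sum(us$scoreable & us$condition == "obs_noUS"))
})

test_that("log normalization has range [0, log 2] and is order-preserving", {
  expect_equal(normalize_scr(0, 1), 0)
  expect_equal(normalize_scr(1, 1), log(2))
  expect_equal(normalize_scr(0.5, 1.0), log(1.5))
  raw <- sort(runif(20))
  norm <- normalize_scr(raw, max(raw))
  expect_true(all(diff(norm) > 0))
  expect_true(all(norm >= 0 & norm <= log(2) + 1e-12))
  expect_error(normalize_scr(1.2, 1.0), "exceeds")
  # all-zero subject: normalization degenerates to zeros
  expect_equal(normalize_scr(c(0, 0), 0), c(0, 0))
})

test_that("the DE non-zero response rule flips exclusion at exactly 5", {
  mk_trials <- function(n_nonzero) {
    de_raw <- c(rep(0.5, n_nonzero), rep(0, 24 - n_nonzero))
    data.frame(trial_index = 1:30,
               phase = c(rep("OFL", 6), rep("DE", 24)),
               condition = c(rep("obs_CS_PLUS", 6),
                             rep(c("dir_CS_PLUS", "dir_CS_MINUS"), 12)),
               raw = c(rep(0.4, 6), de_raw), scoreable = TRUE,
               stringsAsFactors = FALSE)
  }
  expect_true(summarize_scr_subject(mk_trials(4))$excluded)
  expect_false(summarize_scr_subject(mk_trials(5))$excluded)
})

test_that("condition means include zeros and match an independent summation oracle", {
  set.seed(99)
  raw <- round(runif(30, 0, 1), 3)
  raw[raw < 0.2] <- 0
  trials <- data.frame(trial_index = 1:30,
                       phase = rep(c("OFL", "DE"), 15),
                       condition = sample(c("obs_CS_PLUS", "dir_CS_PLUS",
                                            "dir_CS_MINUS"), 30, replace = TRUE),
                       raw = raw, scoreable = TRUE, stringsAsFactors = FALSE)
  s <- summarize_scr_subject(trials)
  expect_equal(s$scr_max, max(raw))
  for (cond in names(s$condition_means)) {
    sel <- trials$condition == cond
    oracle <- sum(log1p(raw[sel] / max(raw))) / sum(sel)
    expect_equal(unname(s$condition_means[[cond]]), oracle, tolerance = 1e-12)
  }
})
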