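test_that("SCR kernel is zero at onset, peak-normalized, and peaks at the closed-form argmax", {
  expect_equal(scr_kernel(0), 0)
  opt <- optimize(scr_kernel, c(0, 10), maximum = TRUE)
  expect_equal(opt$objective, 1.0, tolerance = 1e-9)
  t_star <- log(3.0 / 0.75) * 0.75 * 3.0 / (3.0 - 0.75)
  expect_equal(opt$maximum, t_star, tolerance = 1e-5)
  expect_equal(t_star, 1.386294, tolerance = 1e-6)
  expect_error(scr_kernel(1, rise_tau = 3, decay_tau = 0.75), "smaller")
})

test_that("EDA rendering reduces to the tonic ramp when all responses are silenced", {
  par <- synth_params(eda_noise_sd = 0, amp_us = 0, amp_cs_ofl = 0,
                      amp_cs_plus_aware_de = 0, amp_cs_minus_aware_de = 0,
                      amp_cs_unaware_de = 0)
  tl <- build_timeline(design_config(), "DE", seed = 2)
  x <- render_eda(tl, par, aware = TRUE, seed = 3)
  n <- length(x)
  ramp <- par$tonic_level + par$tonic_drift * (seq_len(n) - 1) / par$fs / 60
  expect_equal(x, ramp, tolerance = 1e-12)
})

test_that("a single rendered response reproduces its amplitude exactly at the peak", {
  cfg <- design_config(n_cs_plus_de = 1, n_cs_minus_de = 1)
  par <- params_deterministic(amp_cs_plus_aware_de = 0.37,
                              amp_cs_minus_aware_de = 0)
  tl <- build_timeline(cfg, "DE", seed = 4, probes = FALSE)
  plus_trial <- tl$trials$index[tl$trials$cs_type == "CS_PLUS"]
  x <- render_eda(tl, par, aware = TRUE, seed = 5, trial_subset = plus_trial)
  expect_equal(max(x) - par$tonic_level, 0.37, tolerance = 1e-9)
})

test_that("event-subset renderings superpose exactly (noise off)", {
  cfg <- design_config()
  par <- params_deterministic()
  tl <- build_timeline(cfg, "OFL", seed = 6)
  idx <- tl$trials$index
  half1 <- idx[idx %% 2 == 1]
  half2 <- idx[idx %% 2 == 0]
  x1 <- render_eda(tl, par, aware = TRUE, seed = 7, trial_subset = half1)
  x2 <- render_eda(tl, par, aware = TRUE, seed = 7, trial_subset = half2)
  xu <- render_eda(tl, par, aware = TRUE, seed = 7)
  tonic <- par$tonic_level + numeric(length(xu))
  expect_equal(x1 + x2 - tonic, xu, tolerance = 1e-9)
})

test_that("rendered EDA stays strictly positive at default parameters", {
  cfg <- design_config()
  par <- synth_params()
  for (seed in 1:12) {
    tl <- build_timeline(cfg, if (seed %% 2) "OFL" else "DE", seed = seed)
    x <- render_eda(tl, par, aware = seed %% 3 == 0, seed = seed + 100)
    expect_gt(min(x), 0)
  }
})

test_that("scored amplitudes track injected amplitudes with unit slope (no noise)", {
  amps <- seq(0.25, 1.0, length.out = 6)
  cfg <- design_config(n_cs_plus_de = 6, n_cs_minus_de = 6)
  recovered <- vapply(seq_along(amps), function(i) {
    par <- params_deterministic(amp_cs_plus_aware_de = amps[i],
                                amp_cs_minus_aware_de = amps[i])
    tl <- build_timeline(cfg, "DE", seed = i)
    x <- render_eda(tl, par, aware = TRUE, seed = i + 50)
    dec <- decompose_eda(x, par$fs)
    tr <- score_scr_trials(dec$phasic, par$fs, tl)
    mean(tr$raw)
  }, numeric(1))
  slope <- coef(lm(recovered ~ amps))[2]
  expect_gte(slope, 0.9)
  expect_lte(slope, 1.1)
})

test_that("EMG with zero burst gain is statistically indistinguishable from baseline", {
  par <- synth_params(burst_gain_ofl = 0, burst_gain_de = 0)
  cfg <- design_config(n_cs_plus_de = 2, n_cs_minus_de = 2)
  tl <- build_timeline(cfg, "DE", seed = 8)
  x <- render_emg(tl, par, aware = TRUE, seed = 9)
  expect_equal(var(x), par$emg_noise_sd^2, tolerance = 0.05)
  expect_equal(mean(x), 0, tolerance = 5 * par$emg_noise_sd / sqrt(length(x)))
})

test_that("noise-free burst magnitudes equal their envelope gains through the scorer", {
  par <- params_deterministic()
  tl <- build_timeline(design_config(), "DE", seed = 10)
  x <- render_emg(tl, par, aware = TRUE, seed = 11)
  sm <- preprocess_emg(x, par$fs)
  tr <- score_fps_trials(sm, par$fs, tl)
  b <- par$burst_cs_boost_aware_de
  gain <- ifelse(grepl("CS_PLUS", tr$condition), par$burst_gain_de * b[["CS_PLUS"]],
                 ifelse(grepl("CS_MINUS", tr$condition),
                        par$burst_gain_de * b[["CS_MINUS"]], par$burst_gain_de))
  expect_true(all(abs(tr$raw / gain - 1) < 0.05))
})

test_that("questionnaire answers classify as constructed, for any seed", {
  for (seed in 1:60) {
    expect_true(classify_contingency(render_questionnaire(TRUE, seed))$aware)
    expect_false(classify_contingency(render_questionnaire(FALSE, seed))$aware)
  }
})

test_that("awareness draws follow the configured binomial law", {
  counts <- vapply(1:1000, function(seed)
    sum(draw_awareness(35, 0.4, seed = seed)), numeric(1))
  # chi-square goodness of fit against Binomial(35, 0.4), tails pooled
  breaks <- c(-Inf, 9:18, Inf)
  obs <- table(cut(counts, breaks))
  pr <- diff(pbinom(c(-Inf, 9:18, Inf), 35, 0.4))
  expect_gt(suppressWarnings(chisq.test(obs, p = pr)$p.value), 0.01)
})

test_that("synthetic Likert ratings land near the published medians", {
  ratings <- do.call(rbind, lapply(1:200, function(seed)
    render_questionnaire(seed %% 2 == 0, seed)$likert_ratings))
  med <- apply(ratings, 2, median)
  expect_true(all(abs(med - c(6, 6, 8, 4, 7)) <= 1))
  expect_true(all(ratings >= 0 & ratings <= 9))
})

test_that("cohort simulation is deterministic under the master seed", {
  cfg <- design_config(n_cs_plus_ofl = 3, n_cs_minus_ofl = 3,
                       n_cs_plus_de = 2, n_cs_minus_de = 2)
  c1 <- simulate_cohort(2, cfg, synth_params(), seed = 12)
  c2 <- simulate_cohort(2, cfg, synth_params(), seed = 12)
  expect_identical(c1$subjects[[1]]$recordings$OFL$channels$eda,
                   c2$subjects[[1]]$recordings$OFL$channels$eda)
  expect_identical(c1$subjects[[2]]$recordings$DE$channels$emg,
                   c2$subjects[[2]]$recordings$DE$channels$emg)
  expect_identical(c1$subjects[[1]]$answers, c2$subjects[[1]]$answers)
  expect_identical(vapply(c1$subjects, `[[`, logical(1), "aware"),
                   vapply(c2$subjects, `[[`, logical(1), "aware"))
})
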