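# Synthetic 2 kHz electrodermal (EDA) and startle-EMG recordings rendered from
# an event timeline, with injectable condition-dependent effect sizes, plus
# synthetic contingency-questionnaire answers. This is what makes every
# downstream stage testable without access to real recordings.

#' Parameters of the synthetic signal generator
#'
#' Effect directions mirror the phenomenon under study: the demonstrator's
#' shock reaction (social US) evokes large SCRs in every observer; a CS+ > CS-
#' electrodermal differential appears in the direct-expression (DE) phase only
#' for contingency-aware observers; startle bursts are stronger in the DE than
#' the OFL phase, and during CSs (vs fixation) in aware observers.
#'
#' @param fs sampling rate, Hz.
#' @param scr_rise_tau,scr_decay_tau biexponential SCR kernel time constants, s.
#' @param scr_latency response latency after event onset, s.
#' @param tonic_level,tonic_drift tonic skin-conductance level (uS) and linear
#'   drift (uS per minute).
#' @param eda_noise_sd Gaussian measurement noise on the EDA channel, uS.
#' @param amp_us mean amplitude of the US-evoked SCR, uS.
#' @param amp_cs_plus_aware_de,amp_cs_minus_aware_de,amp_cs_unaware_de,amp_cs_ofl
#'   mean CS-evoked SCR amplitudes (uS) by phase and awareness.
#' @param response_prob probability that a CS evokes any SCR at all.
#' @param lognormal_amp_cv coefficient of variation of the per-trial lognormal
#'   amplitude variability (also applied to startle burst gains).
#' @param emg_noise_sd baseline EMG noise, mV.
#' @param burst_gain_ofl,burst_gain_de startle burst envelope gain (mV) per phase.
#' @param burst_cs_boost_aware_de multiplicative burst boost during CS+ / CS-
#'   probes in the DE phase for aware observers (fixation = 1).
#' @param burst_latency startle onset latency after probe onset, s.
#' @param burst_duration startle burst duration, s.
#' @param burst_band EMG burst carrier band, Hz (inside the scorer's passband).
#' @param p_aware probability that a simulated observer is contingency-aware.
#' @param seed default master seed for [simulate_cohort()].
#' @return validated list of class `ofl_synth_params`.
#' @export
synth_params <- function(fs = 2000,
                         scr_rise_tau = 0.75, scr_decay_tau = 3.0,
                         scr_latency = 1.5,
                         tonic_level = 5.0, tonic_drift = 0.05,
                         eda_noise_sd = 0.01,
                         amp_us = 0.8,
                         amp_cs_plus_aware_de = 0.30,
                         amp_cs_minus_aware_de = 0.18,
                         amp_cs_unaware_de = 0.18,
                         amp_cs_ofl = 0.15,
                         response_prob = 0.9,
                         lognormal_amp_cv = 0.4,
                         emg_noise_sd = 0.01,
                         burst_gain_ofl = 0.10, burst_gain_de = 0.14,
                         burst_cs_boost_aware_de = c(CS_PLUS = 1.25, CS_MINUS = 1.15),
                         burst_latency = 0.035, burst_duration = 0.1,
                         burst_band = c(30, 300),
                         p_aware = 0.4,
                         seed = NULL) {
  p <- as.list(environment())
  stop_if_not(is_number(p$fs) && p$fs > 2 * 500,
              "'fs' must exceed 1000 Hz so the EMG band is representable")
  stop_if_not(p$scr_rise_tau > 0 && p$scr_decay_tau > 0 &&
                p$scr_rise_tau < p$scr_decay_tau,
              "'scr_rise_tau' must be positive and smaller than 'scr_decay_tau'")
  amps <- c(p$amp_us, p$amp_cs_plus_aware_de, p$amp_cs_minus_aware_de,
            p$amp_cs_unaware_de, p$amp_cs_ofl, p$burst_gain_ofl, p$burst_gain_de)
  stop_if_not(all(amps >= 0), "all amplitudes must be >= 0")
  stop_if_not(p$response_prob >= 0 && p$response_prob <= 1,
              "'response_prob' must be in [0, 1]")
  stop_if_not(p$p_aware >= 0 && p$p_aware <= 1, "'p_aware' must be in [0, 1]")
  structure(p, class = "ofl_synth_params")
}

#' Canonical biexponential (Bateman-type) SCR kernel
#'
#' `h(t) = (exp(-t / decay_tau) - exp(-t / rise_tau)) / c`, peak-normalized so
#' that `max_t h(t) = 1`. The peak occurs at
#' `t* = log(decay/rise) * rise * decay / (decay - rise)`.
#'
#' @param t time since response onset, seconds (vectorized, `t >= 0`).
#' @param rise_tau,decay_tau time constants, s, with `rise_tau < decay_tau`.
#' @return kernel values in `[0, 1]`.
#' @export
scr_kernel <- function(t, rise_tau = 0.75, decay_tau = 3.0) {
  stop_if_not(rise_tau > 0 && decay_tau > 0 && rise_tau < decay_tau,
              "'rise_tau' must be positive and smaller than 'decay_tau'")
  t_peak <- log(decay_tau / rise_tau) * rise_tau * decay_tau / (decay_tau - rise_tau)
  peak <- exp(-t_peak / decay_tau) - exp(-t_peak / rise_tau)
  (exp(-t / decay_tau) - exp(-t / rise_tau)) / peak
}

# Lognormal draws with arithmetic mean `mean` and coefficient of variation `cv`.
rlnorm_mean <- function(n, mean, cv) {
  if (length(mean) == 1) mean <- rep(mean, n)
  if (cv <= 0) return(mean)
  sdlog <- sqrt(log1p(cv^2))
  mean * rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Sampled SCR kernel on the recording grid, renormalized to a discrete peak of
# exactly 1 so that an injected amplitude is reproduced exactly at the peak
# sample.
scr_kernel_samples <- function(fs, rise_tau, decay_tau, span = 40) {
  t <- seq(0, span, by = 1 / fs)
  h <- scr_kernel(t, rise_tau, decay_tau)
  h / max(h)
}

# Condition-specific mean SCR amplitude for each CS trial of a timeline.
cs_amp_means <- function(timeline, params, aware) {
  tr <- timeline$trials
  if (timeline$phase == "OFL") {
    rep(params$amp_cs_ofl, nrow(tr))
  } else if (aware) {
    ifelse(tr$cs_type == "CS_PLUS", params$amp_cs_plus_aware_de,
           params$amp_cs_minus_aware_de)
  } else {
    rep(params$amp_cs_unaware_de, nrow(tr))
  }
}

#' Render the synthetic EDA channel for one phase
#'
#' Tonic level + linear drift + Gaussian noise + a sum of peak-normalized SCR
#' kernels placed `scr_latency` after event onsets. Each CS trial draws a
#' lognormal amplitude around its condition mean and is zeroed with probability
#' `1 - response_prob`. US events always evoke a response of `amp_us` scale; on
#' reinforced trials an additional US-scale response is injected at the CS+
#' onset, emulating the observer's reaction to the demonstrator that the
#' CS-anchored US scoring convention picks up.
#'
#' @param timeline an `ofl_timeline` (one phase).
#' @param params [synth_params()].
#' @param aware logical; contingency-aware observer?
#' @param seed RNG seed.
#' @param trial_subset optional integer vector of trial indices; only responses
#'   belonging to those trials are rendered (tonic baseline and noise are always
#'   rendered). Used to verify superposition.
#' @return numeric vector, uS, of length `ceiling(duration * fs)`.
#' @export
render_eda <- function(timeline, params, aware = TRUE, seed = NULL,
                       trial_subset = NULL) {
  fs <- params$fs
  n <- ceiling(timeline_duration(timeline) * fs)
  tr <- timeline$trials
  keep <- if (is.null(trial_subset)) rep(TRUE, nrow(tr)) else
    tr$index %in% trial_subset

  with_seed(seed, {
    # per-trial CS amplitudes
    amp_cs <- rlnorm_mean(nrow(tr), cs_amp_means(timeline, params, aware),
                          params$lognormal_amp_cv) *
      (runif(nrow(tr)) < params$response_prob)
    # US responses: at the US onset and (same scale) at the reinforced CS onset
    reinf <- which(tr$reinforced)
    amp_us_onset <- rlnorm_mean(length(reinf), params$amp_us,
                                params$lognormal_amp_cv)
    amp_us_cs <- rlnorm_mean(length(reinf), params$amp_us,
                             params$lognormal_amp_cv)
    noise <- if (params$eda_noise_sd > 0) rnorm(n, 0, params$eda_noise_sd) else
      numeric(n)

    onsets <- c(tr$onset[keep],
                tr$onset[reinf][keep[reinf]] + timeline$cfg$us_onset_in_cs,
                tr$onset[reinf][keep[reinf]])
    amps <- c(amp_cs[keep], amp_us_onset[keep[reinf]], amp_us_cs[keep[reinf]])

    tonic <- params$tonic_level +
      params$tonic_drift * (seq_len(n) - 1) / fs / 60
    x <- tonic + noise
    if (length(onsets)) {
      kern <- scr_kernel_samples(fs, params$scr_rise_tau, params$scr_decay_tau)
      idx <- as.integer(round((onsets + params$scr_latency) * fs)) + 1L
      x <- .cpp_add_events(x, idx, amps, kern)
    }
    x
  })
}

# Hann window of length n.
hann_window <- function(n) 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))

# Envelope used to calibrate burst gain, matching the startle scorer's chain:
# 28-500 Hz zero-phase band-pass, rectify, 40 Hz linear-phase FIR smooth.
burst_envelope <- function(x, fs) {
  bp <- signal::butter(4, c(28, 500) / (fs / 2), type = "pass")
  h <- signal::fir1(100, 40 / (fs / 2))
  .cpp_fir_centered(h / sum(h), abs(.cpp_filtfilt(bp$b, bp$a, x)))
}

# Probe table for a timeline: absolute probe onsets and their conditions.
probe_table <- function(timeline) {
  tr <- timeline$trials
  cs <- tr[!is.na(tr$probe_onset), ]
  iti <- tr[!is.na(tr$iti_probe_onset), ]
  rbind(
    if (nrow(cs)) data.frame(trial_index = cs$index, cs_type = cs$cs_type,
                             onset = round_ms(cs$onset + cs$probe_onset),
                             stringsAsFactors = FALSE),
    if (nrow(iti)) data.frame(trial_index = iti$index, cs_type = "FIXATION",
                              onset = round_ms(iti$iti_onset + iti$iti_probe_onset),
                              stringsAsFactors = FALSE))
}

#' Render the synthetic startle-EMG channel for one phase
#'
#' Gaussian baseline noise everywhere; at each startle probe, an additive burst
#' of band-limited noise (carrier filtered to `params$burst_band`), Hann
#' windowed over `burst_duration`, starting `burst_latency` after probe onset.
#' Each burst is calibrated so that its rectified-and-smoothed envelope peak
#' equals `phase gain x condition boost x lognormal trial variability`.
#' For unaware observers (or in the OFL phase) all condition boosts are 1.
#'
#' @inheritParams render_eda
#' @return numeric vector, mV.
#' @export
render_emg <- function(timeline, params, aware = TRUE, seed = NULL) {
  fs <- params$fs
  n <- ceiling(timeline_duration(timeline) * fs)
  probes <- probe_table(timeline)
  phase_gain <- if (timeline$phase == "DE") params$burst_gain_de else
    params$burst_gain_ofl
  boosts <- rep(1, NROW(probes))
  if (timeline$phase == "DE" && aware && NROW(probes)) {
    b <- params$burst_cs_boost_aware_de
    boosts[probes$cs_type == "CS_PLUS"] <- b[["CS_PLUS"]]
    boosts[probes$cs_type == "CS_MINUS"] <- b[["CS_MINUS"]]
  }
  nb <- round(params$burst_duration * fs)
  bp <- signal::butter(4, params$burst_band / (fs / 2), type = "pass")
  w <- hann_window(nb)

  with_seed(seed, {
    x <- if (params$emg_noise_sd > 0) rnorm(n, 0, params$emg_noise_sd) else
      numeric(n)
    if (NROW(probes)) {
      gains <- phase_gain * boosts *
        rlnorm_mean(nrow(probes), 1, params$lognormal_amp_cv)
      for (j in seq_len(nrow(probes))) {
        carrier <- .cpp_filtfilt(bp$b, bp$a, rnorm(nb))
        burst <- carrier * w
        env_peak <- max(burst_envelope(burst, fs))
        burst <- burst / env_peak * gains[j]
        start <- as.integer(round((probes$onset[j] + params$burst_latency) * fs)) + 1L
        len <- min(nb, n - start + 1L)
        if (len > 0)
          x[start:(start + len - 1L)] <- x[start:(start + len - 1L)] + burst[seq_len(len)]
      }
    }
    x
  })
}

#' Synthetic contingency-questionnaire answers
#'
#' Generates answer patterns that [classify_contingency()] labels as requested:
#' aware observers give a correct forced choice backed by either a correct rule
#' report or a uniquely-highest shock-probability rating for the CS+; unaware
#' observers give an incorrect forced choice or an inconsistent answer pattern.
#' Likert ratings of the demonstrator (and self) are drawn around the typical
#' medians observed with this protocol, identically for both groups.
#'
#' @param aware logical ground truth.
#' @param seed RNG seed.
#' @param cs_plus_identity which stimulus is the CS+ (default `"CS_PLUS"`).
#' @return list of class `ofl_answers` with fields `rule_reported`,
#'   `rule_stimulus`, `pct_ratings`, `forced_choice`, `likert_ratings`.
#' @export
render_questionnaire <- function(aware, seed = NULL,
                                 cs_plus_identity = "CS_PLUS") {
  stimuli <- c("CS_PLUS", "CS_MINUS", "FIXATION")
  others <- setdiff(stimuli, cs_plus_identity)
  likert_means <- c(discomfort = 6, strength = 6, naturalness = 8,
                    empathy = 4, identification = 7)
  likert_sds <- c(discomfort = 1.5, strength = 2.2, naturalness = 1.5,
                  empathy = 3.0, identification = 1.5)
  with_seed(seed, {
    likert <- pmin(9L, pmax(0L, as.integer(round(rnorm(5, likert_means,
                                                       likert_sds)))))
    names(likert) <- names(likert_means)
    if (aware) {
      has_rule <- runif(1) < 0.6
      pct <- setNames(c(round(runif(1, 60, 95)), round(runif(1, 5, 40)),
                        round(runif(1, 0, 20))),
                      c(cs_plus_identity, others))
      ans <- list(rule_reported = has_rule,
                  rule_stimulus = if (has_rule) cs_plus_identity else NA_character_,
                  pct_ratings = pct[stimuli],
                  forced_choice = cs_plus_identity)
    } else {
      pattern <- sample(c("wrong_choice", "inconsistent", "tied"), 1)
      if (pattern == "wrong_choice") {
        wrong <- sample(others, 1)
        pct <- setNames(c(round(runif(1, 20, 60)), round(runif(1, 20, 60)),
                          round(runif(1, 0, 30))), c(wrong, setdiff(stimuli, wrong)))
        ans <- list(rule_reported = FALSE, rule_stimulus = NA_character_,
                    pct_ratings = pct[stimuli], forced_choice = wrong)
      } else if (pattern == "inconsistent") {
        wrong <- others[1]
        pct <- setNames(c(80, 30, 10), c(wrong, cs_plus_identity, others[2]))
        ans <- list(rule_reported = TRUE, rule_stimulus = wrong,
                    pct_ratings = pct[stimuli], forced_choice = cs_plus_identity)
      } else {
        tie <- round(runif(1, 40, 60))
        pct <- setNames(c(tie, tie, round(runif(1, 0, 30))),
                        c(cs_plus_identity, others[1], others[2]))
        ans <- list(rule_reported = FALSE, rule_stimulus = NA_character_,
                    pct_ratings = pct[stimuli], forced_choice = cs_plus_identity)
      }
    }
    ans$likert_ratings <- likert
    structure(ans, class = "ofl_answers")
  })
}

#' Draw contingency-awareness ground truth for a cohort
#'
#' @param n number of observers.
#' @param p_aware per-observer probability of awareness.
#' @param seed RNG seed.
#' @return logical vector of length `n`.
#' @export
draw_awareness <- function(n, p_aware, seed = NULL) {
  with_seed(seed, rbinom(n, 1, p_aware) == 1)
}

#' Multichannel physiological recording container
#'
#' @param fs sampling rate, Hz.
#' @param eda,emg channel vectors (either may be `NULL`, but not both; if both
#'   are present they must have equal length).
#' @param subject_id subject identifier.
#' @param aware ground-truth awareness flag (simulation bookkeeping; `NA` for
#'   real data).
#' @return list of class `ofl_recording`.
#' @export
recording <- function(fs, eda = NULL, emg = NULL, subject_id = NA_character_,
                      aware = NA) {
  stop_if_not(!is.null(eda) || !is.null(emg), "at least one channel required")
  if (!is.null(eda) && !is.null(emg))
    stop_if_not(length(eda) == length(emg), "channels must have equal length")
  stop_if_not(all(is.finite(eda %||% 0)) && all(is.finite(emg %||% 0)),
              "channels must be finite")
  n <- length(eda %||% emg)
  structure(list(fs = fs, channels = list(eda = eda, emg = emg),
                 n_samples = n, subject_id = subject_id, role = "observer",
                 aware = aware),
            class = "ofl_recording")
}

#' @export
print.ofl_recording <- function(x, ...) {
  cat(sprintf("<ofl_recording> subject %s: %d samples @ %g Hz (%.1f s), channels: %s\n",
              x$subject_id, x$n_samples, x$fs, x$n_samples / x$fs,
              paste(names(Filter(Negate(is.null), x$channels)), collapse = ", ")))
  invisible(x)
}

# One observer's bundle: fresh timelines, rendered channels, questionnaire.
# `seed_block` is the subject's 7-seed slice of the master stream.
simulate_subject <- function(i, seed_block, cfg, params, channels, aware_i) {
  s <- seed_block
  id <- sprintf("sub-%03d", i)
  tl_ofl <- build_timeline(cfg, "OFL", seed = s[[1]])
  tl_de <- build_timeline(cfg, "DE", seed = s[[2]])
  rec <- lapply(list(OFL = tl_ofl, DE = tl_de), function(tl) {
    k <- if (tl$phase == "OFL") 0L else 1L
    eda <- if ("eda" %in% channels)
      render_eda(tl, params, aware_i, seed = s[[3 + k]]) else NULL
    emg <- if ("emg" %in% channels)
      render_emg(tl, params, aware_i, seed = s[[5 + k]]) else NULL
    recording(params$fs, eda = eda, emg = emg, subject_id = id,
              aware = aware_i)
  })
  list(subject_id = id, aware = aware_i,
       timelines = list(OFL = tl_ofl, DE = tl_de),
       recordings = rec,
       answers = render_questionnaire(aware_i, seed = s[[7]]))
}

#' Simulate a cohort of observers
#'
#' For each observer: draws the awareness flag (unless given), builds fresh
#' OFL and DE timelines, renders the requested channels, and generates
#' questionnaire answers. All per-subject seeds derive deterministically from
#' the master seed.
#'
#' @param n_subjects number of observers.
#' @param cfg [design_config()].
#' @param params [synth_params()].
#' @param seed master seed.
#' @param channels channels to render (subset of `c("eda", "emg")`).
#' @param aware optional logical vector forcing awareness flags.
#' @param out_dir if non-NULL, write events/recordings/answers there.
#' @return list of class `ofl_cohort`; each element has `subject_id`, `aware`,
#'   `timelines` (OFL, DE), `recordings` (OFL, DE) and `answers`.
#' @export
simulate_cohort <- function(n_subjects, cfg = design_config(),
                            params = synth_params(), seed = params$seed,
                            channels = c("eda", "emg"), aware = NULL,
                            out_dir = NULL) {
  stop_if_not(is_count(n_subjects), "'n_subjects' must be >= 1")
  channels <- match.arg(channels, several.ok = TRUE)
  seeds <- derive_seeds(seed, 7 * n_subjects + 1)
  if (is.null(aware))
    aware <- draw_awareness(n_subjects, params$p_aware, seeds[[7 * n_subjects + 1]])
  stop_if_not(length(aware) == n_subjects, "'aware' must have length n_subjects")

  subjects <- lapply(seq_len(n_subjects), function(i)
    simulate_subject(i, seeds[(7 * (i - 1) + 1):(7 * i)], cfg, params,
                     channels, aware[i]))
  cohort <- structure(list(subjects = subjects, cfg = cfg, params = params,
                           seed = seed), class = "ofl_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' @export
print.ofl_cohort <- function(x, ...) {
  cat(sprintf("<ofl_cohort> %d observers (%d aware), seed %s\n",
              length(x$subjects),
              sum(vapply(x$subjects, `[[`, logical(1), "aware")),
              format(x$seed %||% "none")))
  invisible(x)
}
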