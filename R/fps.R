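# Fear-potentiated startle scoring: band-pass -> rectify -> smooth EMG chain,
# windowed peak-minus-baseline magnitude with zero flooring, within-subject
# T-score normalization, condition means and exclusion rules.

#' FPS scoring parameters
#'
#' @param bp_low,bp_high band-pass edges, Hz.
#' @param bp_order Butterworth order of the band-pass (applied zero-phase, so
#'   the effective magnitude response is squared).
#' @param smooth_cutoff low-pass cutoff of the smoothing FIR, Hz.
#' @param fir_order FIR smoother order (even; Hamming design, ~53 dB stopband);
#'   applied with exact group-delay compensation.
#' @param peak_window peak-search window relative to probe onset, s.
#' @param baseline_window baseline window relative to probe onset, s.
#' @param max_nonzero_floor subjects with this many or fewer non-zero startle
#'   responses in the whole experiment are excluded.
#' @param tscore_center,tscore_scale T-score location/scale (50 and 10).
#' @param noisy_rms_factor,noisy_trial_fraction a recording counts as noisy
#'   when more than `noisy_trial_fraction` of its trials have a baseline RMS
#'   above `noisy_rms_factor` times the cohort median baseline RMS.
#' @return validated list of class `ofl_fps_params`.
#' @export
fps_params <- function(bp_low = 28, bp_high = 500, bp_order = 4,
                       smooth_cutoff = 40, fir_order = 100,
                       peak_window = c(0.020, 0.120),
                       baseline_window = c(-0.100, 0.0),
                       max_nonzero_floor = 5,
                       tscore_center = 50, tscore_scale = 10,
                       noisy_rms_factor = 5, noisy_trial_fraction = 0.25) {
  stop_if_not(bp_low < bp_high, "'bp_low' must be below 'bp_high'")
  stop_if_not(peak_window[1] >= baseline_window[2],
              "peak window must follow the baseline window")
  stop_if_not(fir_order %% 2 == 0, "'fir_order' must be even")
  structure(list(bp_low = bp_low, bp_high = bp_high, bp_order = bp_order,
                 smooth_cutoff = smooth_cutoff, fir_order = fir_order,
                 peak_window = peak_window, baseline_window = baseline_window,
                 max_nonzero_floor = max_nonzero_floor,
                 tscore_center = tscore_center, tscore_scale = tscore_scale,
                 noisy_rms_factor = noisy_rms_factor,
                 noisy_trial_fraction = noisy_trial_fraction),
            class = "ofl_fps_params")
}

#' Preprocess raw startle EMG
#'
#' Band-pass filters the signal (Butterworth, zero-phase forward-backward so
#' burst latency is preserved), rectifies it (absolute value) and smooths it
#' with a linear-phase low-pass FIR whose group delay is compensated exactly.
#'
#' @param emg raw EMG series, mV.
#' @param fs sampling rate, Hz; must exceed `2 * bp_high`.
#' @param params [fps_params()].
#' @return smoothed rectified series, mV.
#' @export
preprocess_emg <- function(emg, fs, params = fps_params()) {
  stop_if_not(fs > 2 * params$bp_high,
              sprintf("fs = %g Hz cannot represent the %g-%g Hz band",
                      fs, params$bp_low, params$bp_high))
  bp <- signal::butter(params$bp_order,
                       c(params$bp_low, params$bp_high) / (fs / 2),
                       type = "pass")
  filtered <- .cpp_filtfilt(bp$b, bp$a, emg)
  h <- signal::fir1(params$fir_order, params$smooth_cutoff / (fs / 2))
  h <- h / sum(h)  # unit DC gain so the smoother preserves rectified level
  .cpp_fir_centered(h, abs(filtered))
}

#' Score one startle response
#'
#' Maximum of the smoothed rectified series over `peak_window` minus its mean
#' over `baseline_window` (windows relative to probe onset, half-open in
#' samples). Scored 0 when the peak does not exceed the baseline.
#'
#' @param smoothed preprocessed series from [preprocess_emg()].
#' @param fs sampling rate, Hz.
#' @param probe_onset probe onset, seconds from recording start.
#' @param params [fps_params()].
#' @return raw startle magnitude, mV (>= 0).
#' @export
score_startle <- function(smoothed, fs, probe_onset, params = fps_params()) {
  n <- length(smoothed)
  peak <- idx_range(probe_onset + params$peak_window[1],
                    probe_onset + params$peak_window[2], fs, n)
  base <- idx_range(probe_onset + params$baseline_window[1],
                    probe_onset + params$baseline_window[2], fs, n)
  max(0, max(smoothed[peak]) - mean(smoothed[base]))
}

#' Score all startle probes of a timeline
#'
#' CS probes are labeled `obs_CS_PLUS` / `obs_CS_MINUS` (OFL) or `dir_CS_PLUS`
#' / `dir_CS_MINUS` (DE); intertrial-interval probes `obs_fix` / `dir_fix`.
#' A baseline-window RMS per probe is recorded for the noisy-recording rule.
#'
#' @param smoothed preprocessed series from [preprocess_emg()].
#' @param fs sampling rate, Hz.
#' @param timeline the `ofl_timeline` the recording was rendered from.
#' @param params [fps_params()].
#' @return data.frame with `trial_index`, `phase`, `condition`, `probe_onset`,
#'   `raw`, `baseline_rms`.
#' @export
score_fps_trials <- function(smoothed, fs, timeline, params = fps_params()) {
  probes <- probe_table(timeline)
  if (is.null(probes) || !nrow(probes))
    return(data.frame(trial_index = integer(), phase = character(),
                      condition = character(), probe_onset = numeric(),
                      raw = numeric(), baseline_rms = numeric()))
  prefix <- if (timeline$phase == "OFL") "obs" else "dir"
  cond <- ifelse(probes$cs_type == "FIXATION", paste0(prefix, "_fix"),
                 paste0(prefix, "_", probes$cs_type))
  n <- length(smoothed)
  raw <- numeric(nrow(probes)); brms <- numeric(nrow(probes))
  for (i in seq_len(nrow(probes))) {
    raw[i] <- tryCatch(score_startle(smoothed, fs, probes$onset[i], params),
                       error = function(e) stop("trial ", probes$trial_index[i],
                                                ": ", conditionMessage(e),
                                                call. = FALSE))
    base <- idx_range(probes$onset[i] + params$baseline_window[1],
                      probes$onset[i] + params$baseline_window[2], fs, n)
    brms[i] <- sqrt(mean(smoothed[base]^2))
  }
  data.frame(trial_index = probes$trial_index, phase = timeline$phase,
             condition = cond, probe_onset = probes$onset, raw = raw,
             baseline_rms = brms, stringsAsFactors = FALSE)
}

#' T-score normalization within a participant
#'
#' `T = center + scale * (x - mean(x)) / sd(x)` over all of the subject's
#' scored startle trials pooled across phases (zeros included), with the
#' sample (n-1) standard deviation. Degenerate input (zero variance) maps every
#' score to the center, with a warning.
#'
#' @param raw_scores numeric vector of raw magnitudes for one subject.
#' @param params [fps_params()].
#' @return T-scores (mean `center`, sd `scale` by construction).
#' @export
tscore_normalize <- function(raw_scores, params = fps_params()) {
  stop_if_not(length(raw_scores) >= 2, "need at least 2 scores")
  s <- sd(raw_scores)
  if (!isTRUE(s > 0)) {
    warning("zero variance in startle magnitudes; all T-scores set to ",
            params$tscore_center, call. = FALSE)
    return(rep(params$tscore_center, length(raw_scores)))
  }
  params$tscore_center +
    params$tscore_scale * (raw_scores - mean(raw_scores)) / s
}

#' Per-subject FPS summary: T-scores, condition means, exclusion
#'
#' Pools the subject's probed trials across both phases, T-score normalizes
#' them, averages per condition and applies the exclusion rule (5 or fewer
#' non-zero raw responses in the entire experiment).
#'
#' @param trials trial table from [score_fps_trials()] (both phases combined).
#' @param params [fps_params()].
#' @param subject_id identifier.
#' @return list of class `ofl_fps_subject` with `subject_id`,
#'   `n_nonzero_total`, `excluded`, `exclusion_reason`, `condition_means`
#'   (mean T-score per condition) and the augmented `trials` table.
#' @export
summarize_fps_subject <- function(trials, params = fps_params(),
                                  subject_id = NA_character_) {
  trials$t_score <- tscore_normalize(trials$raw, params)
  n_nonzero <- sum(trials$raw > 0)
  excluded <- n_nonzero <= params$max_nonzero_floor
  cm <- tapply(trials$t_score, trials$condition, mean)
  structure(list(subject_id = subject_id, n_nonzero_total = n_nonzero,
                 excluded = excluded,
                 exclusion_reason = if (excluded) "too_few_nonzero" else "none",
                 condition_means = cm, trials = trials),
            class = "ofl_fps_subject")
}

#' Flag noisy startle recordings across a cohort
#'
#' Operationalizes the visual-inspection exclusion: a subject is flagged when
#' more than `noisy_trial_fraction` of their probed trials have a baseline-
#' window RMS exceeding `noisy_rms_factor` times the cohort median baseline RMS.
#'
#' @param baseline_rms list (one element per subject) of per-trial baseline RMS.
#' @param params [fps_params()].
#' @return logical vector, `TRUE` = noisy.
#' @export
flag_noisy_fps <- function(baseline_rms, params = fps_params()) {
  med <- median(unlist(baseline_rms))
  vapply(baseline_rms, function(r)
    mean(r > params$noisy_rms_factor * med) > params$noisy_trial_fraction,
    logical(1))
}

#' Full FPS scoring for one subject
#'
#' Preprocesses each phase's EMG channel, scores all probes and summarizes.
#'
#' @param recordings named list of `ofl_recording` (`OFL`, `DE`).
#' @param timelines named list of `ofl_timeline` (`OFL`, `DE`).
#' @param params [fps_params()].
#' @param subject_id identifier.
#' @return an `ofl_fps_subject`, see [summarize_fps_subject()].
#' @export
score_fps_subject <- function(recordings, timelines, params = fps_params(),
                              subject_id = NA_character_) {
  trials <- do.call(rbind, lapply(names(timelines), function(ph) {
    rec <- recordings[[ph]]
    sm <- preprocess_emg(rec$channels$emg, rec$fs, params)
    score_fps_trials(sm, rec$fs, timelines[[ph]], params)
  }))
  if (anyNA(trials$raw) || nrow(trials) < 2)
    stop("not enough scoreable startle trials", call. = FALSE)
  summarize_fps_subject(trials, params, subject_id)
}
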