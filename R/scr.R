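# Skin conductance response scoring: tonic/phasic decomposition, windowed
# trough-to-peak amplitude with a response floor, US-trial selection rules,
# within-subject log normalization and condition means with exclusion flags.

#' SCR scoring parameters
#'
#' @param window_start,window_end response window relative to stimulus onset, s
#'   (peak searched in `[onset + window_start, onset + window_end)`).
#' @param baseline_span pre-stimulus baseline span, s (mean over
#'   `[onset - baseline_span, onset)`).
#' @param response_floor amplitudes below this value (uS) are scored as 0.
#' @param min_nonzero_de subjects with fewer non-zero DE-phase responses than
#'   this are excluded.
#' @param decomposition phasic extraction method, see [decompose_eda()].
#' @param fs_ds internal decomposition grid rate, Hz.
#' @param lambda sparsity weight of the convex driver deconvolution (relative
#'   to the Lipschitz constant of the quadratic term).
#' @param knot_spacing tonic spline knot spacing, s.
#' @param rise_tau,decay_tau SCR kernel time constants assumed by the
#'   deconvolution, s.
#' @return validated list of class `ofl_scr_params`.
#' @export
scr_params <- function(window_start = 0.0, window_end = 6.0,
                       baseline_span = 2.0, response_floor = 0.2,
                       min_nonzero_de = 5,
                       decomposition = c("convex_sparse", "highpass_baseline"),
                       fs_ds = 10, lambda = 2e-3, knot_spacing = 10,
                       rise_tau = 0.75, decay_tau = 3.0) {
  decomposition <- match.arg(decomposition)
  stop_if_not(window_end > window_start, "'window_end' must exceed 'window_start'")
  stop_if_not(response_floor >= 0, "'response_floor' must be >= 0")
  structure(list(window_start = window_start, window_end = window_end,
                 baseline_span = baseline_span, response_floor = response_floor,
                 min_nonzero_de = min_nonzero_de, decomposition = decomposition,
                 fs_ds = fs_ds, lambda = lambda, knot_spacing = knot_spacing,
                 rise_tau = rise_tau, decay_tau = decay_tau),
            class = "ofl_scr_params")
}

# Sample indices covering the half-open time interval [a, b); sample i sits at
# time (i - 1) / fs and belongs iff a <= (i - 1) / fs < b.
idx_range <- function(a, b, fs, n = Inf) {
  i0 <- ceiling(a * fs - 1e-9) + 1
  i1 <- ceiling(b * fs - 1e-9)
  if (i0 < 1 || i1 > n)
    stop(sprintf("window [%.3f, %.3f) s extends past the recording", a, b),
         call. = FALSE)
  seq.int(i0, i1)
}

# FFT convolution helpers for the driver deconvolution. H is fft of the
# zero-padded kernel; nfft the padded length; n the signal length.
conv_K <- function(d, H, nfft, n) {
  D <- fft(c(d, numeric(nfft - length(d))))
  Re(fft(D * H, inverse = TRUE))[seq_len(n)] / nfft
}
conv_Kt <- function(r, H, nfft, n) {
  R <- fft(c(r, numeric(nfft - length(r))))
  Re(fft(R * Conj(H), inverse = TRUE))[seq_len(n)] / nfft
}

# FISTA for  min_{d >= 0}  0.5 ||K d - r||^2 + lambda * sum(d).
# `mask` freezes entries at zero (used for the debiasing pass).
fista_nonneg <- function(r, H, nfft, n, lambda, L, maxit, d0 = numeric(n),
                         mask = NULL) {
  d <- d0; y <- d0; tk <- 1
  for (it in seq_len(maxit)) {
    g <- conv_Kt(conv_K(y, H, nfft, n) - r, H, nfft, n)
    d_new <- pmax(0, y - (g + lambda) / L)
    if (!is.null(mask)) d_new[mask] <- 0
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    y <- d_new + (tk - 1) / t_new * (d_new - d)
    d <- d_new; tk <- t_new
  }
  d
}

#' Decompose an EDA series into tonic and phasic components
#'
#' The default `convex_sparse` method solves a sparse-driver deconvolution: the
#' phasic component is modeled as a non-negative sudomotor driver convolved
#' with a biexponential SCR kernel, the tonic component as a slow cubic
#' B-spline; the non-negative L1-penalized least-squares problem is solved by
#' proximal-gradient iteration (with a final unpenalized refit on the recovered
#' support to remove shrinkage bias), alternating with the tonic spline fit.
#' The solve runs on an internal low-rate grid (`params$fs_ds`; electrodermal
#' activity is band-limited well below it) and the components are interpolated
#' back to the recording rate.
#'
#' `highpass_baseline` is a simpler approximation: a running-median tonic
#' estimate (smoothed) is subtracted and the positive remainder is taken as
#' phasic.
#'
#' @param eda EDA series, uS.
#' @param fs sampling rate, Hz.
#' @param method decomposition method.
#' @param params [scr_params()] (supplies the method hyperparameters).
#' @return list of class `ofl_eda_decomposition` with `tonic`, `phasic`,
#'   `residual` (all at `fs`), `driver` and `fs_ds` (decomposition grid), such
#'   that `eda = tonic + phasic + residual` and `phasic >= -1e-6`.
#' @export
decompose_eda <- function(eda, fs, method = NULL, params = scr_params()) {
  stop_if_not(all(is.finite(eda)), "'eda' contains non-finite samples")
  method <- method %||% params$decomposition
  method <- match.arg(method, c("convex_sparse", "highpass_baseline"))
  n_full <- length(eda)

  fac <- max(1L, round(fs / params$fs_ds))
  fs_ds <- fs / fac
  n_ds <- floor(n_full / fac)
  x_ds <- if (fac > 1)
    .colMeans(eda[seq_len(n_ds * fac)], fac, n_ds) else eda
  t_ds <- (seq_len(n_ds) - 1) / fs_ds
  t_full <- (seq_len(n_full) - 1) / fs

  if (method == "highpass_baseline") {
    k <- min(n_ds - (1 - n_ds %% 2), 2 * floor(8 * fs_ds / 2) + 1)
    tonic_ds <- as.numeric(stats::runmed(x_ds, k))
    # moving-average smoothing with edge renormalization (zero padding would
    # otherwise pull the tonic estimate down at the recording boundaries)
    sm <- max(1L, floor(4 * fs_ds)); w <- rep(1 / sm, sm)
    tonic_ds <- as.numeric(.cpp_fir_centered(w, tonic_ds)) /
      .cpp_fir_centered(w, rep(1, n_ds))
    tonic <- approx(t_ds, tonic_ds, xout = t_full, rule = 2)$y
    phasic <- pmax(eda - tonic, 0)
    return(structure(list(tonic = tonic, phasic = phasic,
                          residual = eda - tonic - phasic,
                          driver = NULL, fs = fs, fs_ds = fs_ds,
                          method = method),
                     class = "ofl_eda_decomposition"))
  }

  # convex sparse-driver deconvolution against the biexponential kernel, on a
  # robust running-quantile tonic baseline (a low quantile over long blocks is
  # insensitive to the transient, strictly positive SCR bumps, so the driver --
  # not the baseline -- captures the responses)
  kern <- scr_kernel(seq(0, min(40, t_ds[n_ds]), by = 1 / fs_ds),
                     params$rise_tau, params$decay_tau) / fs_ds
  nfft <- stats::nextn(n_ds + length(kern), 2)
  H <- fft(c(kern, numeric(nfft - length(kern))))
  L <- max(Mod(H)^2)

  blk <- max(2L, round(params$knot_spacing * fs_ds))
  nb <- max(1L, floor(n_ds / blk))
  tb <- ((seq_len(nb) - 0.5) * blk) / fs_ds
  quantile_baseline <- function(y) {
    q <- vapply(seq_len(nb), function(i)
      unname(quantile(y[((i - 1) * blk + 1):min(i * blk, n_ds)], 0.25)),
      numeric(1))
    if (nb >= 2) approx(tb, q, xout = t_ds, rule = 2)$y else rep(q, n_ds)
  }

  lambda <- params$lambda * L * stats::mad(diff(x_ds)) * sqrt(fs_ds)
  # alternate: a low-quantile baseline is still slightly inflated by response
  # tails on the first pass, so re-estimate it on the driver-explained signal
  tonic_ds <- quantile_baseline(x_ds)
  d <- numeric(n_ds)
  for (pass in 1:2) {
    d <- fista_nonneg(x_ds - tonic_ds, H, nfft, n_ds, lambda, L, maxit = 50,
                      d0 = d)
    # debias: refit without the L1 penalty on the recovered support
    d <- fista_nonneg(x_ds - tonic_ds, H, nfft, n_ds, lambda = 0, L,
                      maxit = 25, d0 = d, mask = d <= 0)
    tonic_ds <- quantile_baseline(x_ds - conv_K(d, H, nfft, n_ds))
  }
  # driver and kernel are non-negative, so the phasic component is too (up to
  # FFT round-off, well inside the -1e-6 tolerance)
  phasic_ds <- conv_K(d, H, nfft, n_ds)
  tonic <- approx(t_ds, tonic_ds, xout = t_full, rule = 2)$y
  phasic <- approx(t_ds, phasic_ds, xout = t_full, rule = 2)$y
  structure(list(tonic = tonic, phasic = phasic,
                 residual = eda - tonic - phasic,
                 driver = d, fs = fs, fs_ds = fs_ds, method = method),
            class = "ofl_eda_decomposition")
}

#' Score one SCR trial from the phasic component
#'
#' Trough-to-peak amplitude: maximum of the phasic series over
#' `[onset + window_start, onset + window_end)` minus its mean over
#' `[onset - baseline_span, onset)`. Amplitudes below `response_floor`
#' (including negative differences) are scored 0.
#'
#' @param phasic phasic EDA series, uS.
#' @param fs sampling rate, Hz.
#' @param onset stimulus onset, seconds from recording start.
#' @param params [scr_params()].
#' @return raw amplitude, uS (0 = no response).
#' @export
score_scr_trial <- function(phasic, fs, onset, params = scr_params()) {
  n <- length(phasic)
  resp <- idx_range(onset + params$window_start, onset + params$window_end, fs, n)
  base <- idx_range(onset - params$baseline_span, onset, fs, n)
  amp <- max(phasic[resp]) - mean(phasic[base])
  if (amp < params$response_floor) 0 else amp
}

#' Score all CS trials of a timeline
#'
#' Every CS trial is scored at its onset and labeled `obs_CS_PLUS` /
#' `obs_CS_MINUS` (OFL phase) or `dir_CS_PLUS` / `dir_CS_MINUS` (DE phase).
#' For the OFL phase, US-condition rows (`obs_US` for reinforced, `obs_noUS`
#' for unreinforced CS+) are appended via [score_us_trials()].
#'
#' @param phasic phasic EDA series, uS.
#' @param fs sampling rate, Hz.
#' @param timeline the `ofl_timeline` the recording was rendered from.
#' @param params [scr_params()].
#' @return data.frame with columns `trial_index`, `phase`, `condition`,
#'   `raw` (uS; `NA` when not scoreable) and `scoreable`.
#' @export
score_scr_trials <- function(phasic, fs, timeline, params = scr_params()) {
  tr <- timeline$trials
  prefix <- if (timeline$phase == "OFL") "obs" else "dir"
  cond <- paste0(prefix, "_", tr$cs_type)
  raw <- vapply(seq_len(nrow(tr)), function(i) {
    tryCatch(score_scr_trial(phasic, fs, tr$onset[i], params),
             error = function(e) stop("trial ", tr$index[i], ": ",
                                      conditionMessage(e), call. = FALSE))
  }, numeric(1))
  out <- data.frame(trial_index = tr$index, phase = timeline$phase,
                    condition = cond, raw = raw, scoreable = TRUE,
                    stringsAsFactors = FALSE)
  if (timeline$phase == "OFL")
    out <- rbind(out, score_us_trials(phasic, fs, timeline, params))
  rownames(out) <- NULL
  out
}

#' Score US / no-US observation trials
#'
#' Responses to the (observed) US are measured only on CS+ trials that carry no
#' startle probe during the CS and none in the immediately following intertrial
#' interval; reinforced trials are labeled `obs_US`, unreinforced `obs_noUS`.
#' The scoring window is identical to CS scoring, anchored at CS onset.
#'
#' @inheritParams score_scr_trials
#' @return data.frame in the [score_scr_trials()] layout (non-scoreable trials
#'   keep `raw = NA`).
#' @export
score_us_trials <- function(phasic, fs, timeline, params = scr_params()) {
  stop_if_not(timeline$phase == "OFL", "US trials exist only in the OFL phase")
  tr <- timeline$trials[timeline$trials$cs_type == "CS_PLUS", ]
  scoreable <- is.na(tr$probe_onset) & is.na(tr$iti_probe_onset)
  raw <- rep(NA_real_, nrow(tr))
  raw[scoreable] <- vapply(which(scoreable), function(i)
    score_scr_trial(phasic, fs, tr$onset[i], params), numeric(1))
  data.frame(trial_index = tr$index, phase = "OFL",
             condition = ifelse(tr$reinforced, "obs_US", "obs_noUS"),
             raw = raw, scoreable = scoreable, stringsAsFactors = FALSE)
}

#' Within-subject log normalization of SCR amplitudes
#'
#' `log(1 + raw / scr_max)` (natural logarithm), where `scr_max` is the
#' subject's largest scored response. Monotone in `raw`, with range
#' `[0, log(2)]`.
#'
#' @param raw raw amplitude(s), uS.
#' @param scr_max subject maximum response, uS.
#' @return normalized magnitude(s).
#' @export
normalize_scr <- function(raw, scr_max) {
  if (any(raw > scr_max, na.rm = TRUE))
    stop("'raw' exceeds 'scr_max'; scr_max must be the subject maximum",
         call. = FALSE)
  if (!isTRUE(scr_max > 0)) return(ifelse(is.na(raw), NA_real_, 0))
  log1p(raw / scr_max)
}

#' Per-subject SCR summary: normalization, condition means, exclusion
#'
#' Computes the subject maximum over all scored trials, normalizes every trial,
#' averages normalized magnitudes per condition (no-responses enter as zeros),
#' and flags the subject for exclusion when fewer than `params$min_nonzero_de`
#' non-zero responses occurred in the DE phase.
#'
#' @param trials trial table from [score_scr_trials()] (both phases combined).
#' @param params [scr_params()].
#' @param subject_id identifier carried into the result.
#' @return list of class `ofl_scr_subject` with `subject_id`, `scr_max`,
#'   `n_nonzero_de`, `excluded`, `condition_means` and the augmented `trials`
#'   table (normalized column added).
#' @export
summarize_scr_subject <- function(trials, params = scr_params(),
                                  subject_id = NA_character_) {
  scored <- trials[trials$scoreable & !is.na(trials$raw), ]
  scr_max <- if (nrow(scored)) max(scored$raw) else 0
  trials$normalized <- normalize_scr(trials$raw, scr_max)
  de <- trials[trials$phase == "DE" & trials$scoreable, ]
  n_nonzero_de <- sum(de$raw > 0, na.rm = TRUE)
  cm <- tapply(trials$normalized[trials$scoreable],
               trials$condition[trials$scoreable], mean)
  list_out <- list(subject_id = subject_id, scr_max = scr_max,
                   n_nonzero_de = n_nonzero_de,
                   excluded = n_nonzero_de < params$min_nonzero_de,
                   condition_means = cm, trials = trials)
  structure(list_out, class = "ofl_scr_subject")
}

#' Full SCR scoring for one subject
#'
#' Decomposes each phase's EDA channel, scores all trials and summarizes.
#'
#' @param recordings named list of `ofl_recording` (`OFL`, `DE`).
#' @param timelines named list of `ofl_timeline` (`OFL`, `DE`).
#' @param params [scr_params()].
#' @param subject_id identifier.
#' @return an `ofl_scr_subject`, see [summarize_scr_subject()].
#' @export
score_scr_subject <- function(recordings, timelines, params = scr_params(),
                              subject_id = NA_character_) {
  trials <- do.call(rbind, lapply(names(timelines), function(ph) {
    rec <- recordings[[ph]]
    dec <- decompose_eda(rec$channels$eda, rec$fs, params = params)
    score_scr_trials(dec$phasic, rec$fs, timelines[[ph]], params)
  }))
  summarize_scr_subject(trials, params, subject_id)
}
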