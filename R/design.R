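# Experimental design generation: constrained CS sequences, partial
# reinforcement, startle-probe placement, and absolute-time event lists for the
# two phases (OFL = observational fear learning, DE = direct expression) of the
# observational conditioning protocol.

#' Design configuration for the two-phase conditioning experiment
#'
#' Collects all counts, durations and ratios that define the experimental
#' timeline. Defaults encode the reference protocol: 24 CS+ / 24 CS- trials in
#' the OFL phase, 12 of each in the DE phase, 50% reinforcement of CS+ in OFL
#' (first and last CS+ always reinforced), 9 s CS duration, intertrial
#' intervals uniform on 10-15 s, a shock train starting 7.5 s after CS onset
#' (five 1 ms pulses, 200 ms apart), startle probes on half of the CS trials
#' (onset 6.0, 6.5 or 7.0 s after CS onset) and a quarter of the intertrial
#' intervals (onset 2.0-4.5 s after fixation onset), and no more than two
#' consecutive presentations of the same CS.
#'
#' @param n_cs_plus_ofl,n_cs_minus_ofl trial counts for the OFL phase.
#' @param n_cs_plus_de,n_cs_minus_de trial counts for the DE phase.
#' @param reinforcement_ratio fraction of OFL CS+ trials that are reinforced.
#' @param cs_duration CS display duration, seconds.
#' @param iti_range intertrial interval range, seconds (uniform draw).
#' @param us_onset_in_cs shock-train onset relative to CS onset, seconds.
#' @param us_n_pulses,us_pulse_duration,us_pulse_latency shock-train shape:
#'   number of pulses, single-pulse duration (s), inter-pulse latency (s).
#' @param probe_cs_fraction fraction of CS trials carrying a startle probe.
#' @param probe_cs_onsets admissible probe onsets relative to CS onset, seconds.
#' @param probe_iti_fraction fraction of intertrial intervals carrying a probe.
#' @param probe_iti_onset_range probe onset range relative to fixation onset.
#' @param probe_duration acoustic probe duration, seconds.
#' @param max_run_length maximum run of identical CS types.
#' @param seed default seed used by [build_timeline()] when none is given.
#' @return a validated list of class `ofl_design_config`.
#' @export
design_config <- function(n_cs_plus_ofl = 24, n_cs_minus_ofl = 24,
                          n_cs_plus_de = 12, n_cs_minus_de = 12,
                          reinforcement_ratio = 0.5,
                          cs_duration = 9.0,
                          iti_range = c(10.0, 15.0),
                          us_onset_in_cs = 7.5,
                          us_n_pulses = 5,
                          us_pulse_duration = 0.001,
                          us_pulse_latency = 0.200,
                          probe_cs_fraction = 0.5,
                          probe_cs_onsets = c(6.0, 6.5, 7.0),
                          probe_iti_fraction = 0.25,
                          probe_iti_onset_range = c(2.0, 4.5),
                          probe_duration = 0.05,
                          max_run_length = 2,
                          seed = NULL) {
  cfg <- list(
    n_cs_plus_ofl = n_cs_plus_ofl, n_cs_minus_ofl = n_cs_minus_ofl,
    n_cs_plus_de = n_cs_plus_de, n_cs_minus_de = n_cs_minus_de,
    reinforcement_ratio = reinforcement_ratio, cs_duration = cs_duration,
    iti_range = iti_range, us_onset_in_cs = us_onset_in_cs,
    us_n_pulses = us_n_pulses, us_pulse_duration = us_pulse_duration,
    us_pulse_latency = us_pulse_latency,
    probe_cs_fraction = probe_cs_fraction, probe_cs_onsets = probe_cs_onsets,
    probe_iti_fraction = probe_iti_fraction,
    probe_iti_onset_range = probe_iti_onset_range,
    probe_duration = probe_duration,
    max_run_length = max_run_length, seed = seed)
  validate_design_config(cfg)
  structure(cfg, class = "ofl_design_config")
}

validate_design_config <- function(cfg) {
  for (f in c("n_cs_plus_ofl", "n_cs_minus_ofl", "n_cs_plus_de",
              "n_cs_minus_de", "us_n_pulses", "max_run_length"))
    stop_if_not(is_count(cfg[[f]]), sprintf("'%s' must be a positive integer", f))
  stop_if_not(is_number(cfg$reinforcement_ratio) &&
                cfg$reinforcement_ratio > 0 && cfg$reinforcement_ratio <= 1,
              "'reinforcement_ratio' must be in (0, 1]")
  stop_if_not(length(cfg$iti_range) == 2 && cfg$iti_range[1] <= cfg$iti_range[2],
              "'iti_range' must be an ordered pair")
  stop_if_not(all(cfg$probe_cs_onsets < cfg$cs_duration),
              "probe onsets must fall inside the CS interval")
  stop_if_not(cfg$us_onset_in_cs < cfg$cs_duration,
              "'us_onset_in_cs' must fall inside the CS interval")
  stop_if_not(is_number(cfg$probe_cs_fraction) && cfg$probe_cs_fraction >= 0 &&
                cfg$probe_cs_fraction <= 1, "'probe_cs_fraction' must be in [0, 1]")
  stop_if_not(is_number(cfg$probe_iti_fraction) && cfg$probe_iti_fraction >= 0 &&
                cfg$probe_iti_fraction <= 1, "'probe_iti_fraction' must be in [0, 1]")
  invisible(cfg)
}

#' Total span of the shock pulse train
#'
#' Span from first pulse onset to last pulse offset, reported to one decimal
#' place in seconds: `(n_pulses - 1) * latency + pulse_duration`.
#'
#' @param n_pulses number of pulses (>= 1).
#' @param pulse_duration single-pulse duration, seconds.
#' @param latency inter-pulse onset latency, seconds.
#' @return duration in seconds, rounded to 1 decimal.
#' @examples
#' us_train_duration(5, 0.001, 0.200) # 0.8
#' @export
us_train_duration <- function(n_pulses, pulse_duration, latency) {
  stop_if_not(is_count(n_pulses), "'n_pulses' must be a positive integer")
  round((n_pulses - 1) * latency + pulse_duration, 1)
}

#' Generate a pseudo-random CS sequence under a run-length constraint
#'
#' Produces an ordering of `n_plus` CS+ and `n_minus` CS- trials in which no
#' CS type repeats more than `max_run_length` times in a row. Sampling is a
#' randomized constructive scheme with feasibility pruning, so every emitted
#' sequence satisfies the constraints and generation never dead-ends.
#'
#' @param n_plus,n_minus trial counts per CS type (>= 1).
#' @param max_run_length maximum run of identical CS types (>= 1).
#' @param seed RNG seed; a fixed seed gives a reproducible sequence.
#' @return character vector of `"CS_PLUS"` / `"CS_MINUS"`.
#' @export
generate_cs_sequence <- function(n_plus, n_minus, max_run_length = 2,
                                 seed = NULL) {
  stop_if_not(is_count(n_plus) && is_count(n_minus),
              "'n_plus' and 'n_minus' must be positive integers")
  stop_if_not(is_count(max_run_length), "'max_run_length' must be >= 1")
  k <- max_run_length
  if (n_plus > k * (n_minus + 1) || n_minus > k * (n_plus + 1))
    stop("infeasible constraint set: no sequence of ", n_plus, " CS+ and ",
         n_minus, " CS- exists with maximum run length ", k, call. = FALSE)
  labels <- c("CS_PLUS", "CS_MINUS")
  with_seed(seed, {
    rem <- c(CS_PLUS = n_plus, CS_MINUS = n_minus)
    out <- character(n_plus + n_minus)
    run_label <- ""
    run_len <- 0L
    for (i in seq_along(out)) {
      ok <- vapply(labels, function(L) {
        if (rem[[L]] == 0L) return(FALSE)
        r <- if (L == run_label) run_len + 1L else 1L
        if (r > k) return(FALSE)
        p <- rem[[L]] - 1L                  # remaining of L after placing it
        m <- rem[[setdiff(labels, L)]]      # remaining of the other type
        # completable iff the other type can break all future runs of L and
        # vice versa, given the trailing run r of L
        m <= k * (p + 1) && p <= k * m + (k - r)
      }, logical(1))
      cand <- labels[ok]
      pick <- if (length(cand) == 1L) cand else
        sample(cand, 1L, prob = rem[cand])
      out[i] <- pick
      rem[[pick]] <- rem[[pick]] - 1L
      run_len <- if (pick == run_label) run_len + 1L else 1L
      run_label <- pick
    }
    out
  })
}

#' Assign partial reinforcement to the CS+ trials of a sequence
#'
#' Selects `round(ratio * n_CS+)` CS+ trials (ties-to-even rounding) for
#' reinforcement. The first and the last CS+ presentation are always
#' reinforced; the remainder is drawn at random from the middle CS+ trials.
#'
#' @param sequence character vector of CS types (from [generate_cs_sequence()]).
#' @param ratio reinforced fraction of CS+ trials.
#' @param seed RNG seed.
#' @return sorted integer vector of reinforced trial indices (into `sequence`).
#' @export
assign_reinforcement <- function(sequence, ratio = 0.5, seed = NULL) {
  plus <- which(sequence == "CS_PLUS")
  stop_if_not(length(plus) >= 2, "need at least 2 CS+ trials")
  n_reinf <- round(ratio * length(plus))
  if (n_reinf < 2)
    stop("reinforcement ratio ", ratio, " yields fewer than the 2 reinforced ",
         "trials required by the first/last rule", call. = FALSE)
  stop_if_not(n_reinf <= length(plus), "cannot reinforce more CS+ than exist")
  ends <- c(plus[1], plus[length(plus)])
  middle <- setdiff(plus, ends)
  extra <- if (n_reinf - 2 > 0)
    with_seed(seed, sample(middle, n_reinf - 2)) else integer(0)
  sort(c(ends, extra))
}

#' Build the full event timeline for one experimental phase
#'
#' Generates the CS sequence, reinforcement schedule (OFL phase only),
#' intertrial intervals, absolute trial onsets, US pulse-train events and --
#' unless `probes = FALSE` -- the startle-probe placement. Each phase starts
#' with a lead-in fixation interval (one ITI draw) so that every trial has a
#' pre-stimulus baseline. All event times are generated on a 1 ms grid
#' (presentation-timer resolution), which makes the 3-decimal events file
#' lossless.
#'
#' @param cfg an [design_config()] object.
#' @param phase `"OFL"` or `"DE"`.
#' @param seed RNG seed; defaults to `cfg$seed`.
#' @param probes assign startle probes (default `TRUE`).
#' @return an object of class `ofl_timeline`: a list with `phase`, `lead_in`
#'   (seconds), `trials` (one row per trial) and `events` (flattened event
#'   table, sorted by onset).
#' @export
build_timeline <- function(cfg, phase = c("OFL", "DE"), seed = cfg$seed,
                           probes = TRUE) {
  phase <- match.arg(phase)
  validate_design_config(cfg)
  seeds <- derive_seeds(seed, 4)
  if (phase == "OFL") {
    n_plus <- cfg$n_cs_plus_ofl; n_minus <- cfg$n_cs_minus_ofl
  } else {
    n_plus <- cfg$n_cs_plus_de; n_minus <- cfg$n_cs_minus_de
  }
  cs <- generate_cs_sequence(n_plus, n_minus, cfg$max_run_length, seeds[[1]])
  reinforced <- rep(FALSE, length(cs))
  if (phase == "OFL")
    reinforced[assign_reinforcement(cs, cfg$reinforcement_ratio, seeds[[2]])] <- TRUE

  n <- length(cs)
  itis <- with_seed(seeds[[3]],
                    round_ms(runif(n + 1, cfg$iti_range[1], cfg$iti_range[2])))
  lead_in <- itis[1]
  onsets <- lead_in + cumsum(c(0, head(itis[-1], -1) + cfg$cs_duration))
  trials <- data.frame(
    index = seq_len(n), phase = phase, cs_type = cs,
    onset = round_ms(onsets), duration = cfg$cs_duration,
    reinforced = reinforced,
    probe_onset = NA_real_,
    iti_onset = round_ms(onsets + cfg$cs_duration),
    iti_duration = itis[-1],
    iti_probe_onset = NA_real_,
    stringsAsFactors = FALSE)
  tl <- structure(list(phase = phase, cfg = cfg, lead_in = lead_in,
                       trials = trials, events = NULL),
                  class = "ofl_timeline")
  if (probes) tl <- assign_probes(tl, cfg, seeds[[4]])
  tl$events <- timeline_events(tl)
  tl
}

#' Assign startle probes to a timeline
#'
#' Places probes on `floor(probe_cs_fraction * n_CS)` CS trials, balanced
#' across CS+ and CS- (and, within reinforced vs unreinforced CS+, split as
#' evenly as possible so that US scoring retains unprobed trials of both
#' kinds), with onsets drawn from `cfg$probe_cs_onsets`. Additionally probes
#' `floor(probe_iti_fraction * n_ITI)` intertrial intervals with onsets uniform
#' in `cfg$probe_iti_onset_range` (the 4.5 s cap against the 10 s minimum ITI
#' keeps ITI probes clear of the next CS).
#'
#' @param timeline an `ofl_timeline` (single phase).
#' @param cfg an [design_config()] object.
#' @param seed RNG seed.
#' @return the timeline with probe columns filled and events rebuilt.
#' @export
assign_probes <- function(timeline, cfg = timeline$cfg, seed = NULL) {
  tr <- timeline$trials
  n_cs <- nrow(tr)
  n_probed <- floor(cfg$probe_cs_fraction * n_cs)
  per_type <- n_probed %/% 2L
  seeds <- derive_seeds(seed, 5)

  pick_stratified <- function(idx, strata, n_take, s) {
    # split n_take across strata proportionally (largest remainder), then
    # sample within each stratum
    if (n_take == 0 || length(idx) == 0) return(integer(0))
    lev <- unique(strata)
    sizes <- vapply(lev, function(l) sum(strata == l), integer(1))
    quota <- n_take * sizes / length(idx)
    take <- floor(quota)
    rem <- n_take - sum(take)
    if (rem > 0) {
      ord <- order(quota - take, decreasing = TRUE)
      take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1L
    }
    with_seed(s, unlist(lapply(seq_along(lev), function(i) {
      pool <- idx[strata == lev[i]]
      if (take[i] >= length(pool)) pool else sample(pool, take[i])
    }), use.names = FALSE))
  }

  plus_idx <- which(tr$cs_type == "CS_PLUS")
  minus_idx <- which(tr$cs_type == "CS_MINUS")
  extra <- n_probed - 2L * per_type
  take_plus <- per_type + if (extra > 0)
    with_seed(seeds[[1]], sample(c(1L, 0L), 1)) else 0L
  take_minus <- n_probed - take_plus
  probed <- c(
    pick_stratified(plus_idx, tr$reinforced[plus_idx], min(take_plus, length(plus_idx)),
                    seeds[[2]]),
    with_seed(seeds[[5]], if (take_minus >= length(minus_idx)) minus_idx else
      sample(minus_idx, take_minus)))
  tr$probe_onset <- NA_real_
  if (length(probed))
    tr$probe_onset[probed] <- with_seed(
      seeds[[3]], sample(cfg$probe_cs_onsets, length(probed), replace = TRUE))

  # ITI probes make the following trial's US response unscoreable, so they are
  # likewise stratified: equal counts fall on CS-unprobed reinforced and
  # CS-unprobed unreinforced CS+ trials, keeping the scoreable obs US / no-US
  # trial counts equal
  n_iti_probed <- floor(cfg$probe_iti_fraction * n_cs)
  tr$iti_probe_onset <- NA_real_
  if (n_iti_probed > 0) {
    unprobed_plus <- tr$cs_type == "CS_PLUS" & is.na(tr$probe_onset)
    a_idx <- which(unprobed_plus & tr$reinforced)
    b_idx <- which(unprobed_plus & !tr$reinforced)
    c_idx <- setdiff(seq_len(n_cs), c(a_idx, b_idx))
    take_ab <- min(round(n_iti_probed * length(a_idx) / n_cs),
                   n_iti_probed %/% 2, length(a_idx), length(b_idx))
    with_seed(seeds[[4]], {
      iti_probed <- c(
        if (take_ab > 0) sample(a_idx, take_ab),
        if (take_ab > 0) sample(b_idx, take_ab),
        sample(c_idx, min(n_iti_probed - 2 * take_ab, length(c_idx))))
      tr$iti_probe_onset[iti_probed] <-
        round_ms(runif(length(iti_probed), cfg$probe_iti_onset_range[1],
                       cfg$probe_iti_onset_range[2]))
    })
  }
  timeline$trials <- tr
  timeline$events <- timeline_events(timeline)
  timeline
}

# Flatten a timeline into the sorted event table.
timeline_events <- function(timeline) {
  tr <- timeline$trials
  cfg <- timeline$cfg
  ev <- list(data.frame(onset = 0, duration = timeline$lead_in,
                        trial_index = NA_integer_, phase = timeline$phase,
                        kind = "FIXATION", reinforced = FALSE, probe = FALSE,
                        stringsAsFactors = FALSE))
  ev[[length(ev) + 1]] <- data.frame(
    onset = tr$onset, duration = tr$duration, trial_index = tr$index,
    phase = tr$phase, kind = tr$cs_type, reinforced = tr$reinforced,
    probe = FALSE, stringsAsFactors = FALSE)
  ev[[length(ev) + 1]] <- data.frame(
    onset = tr$iti_onset, duration = tr$iti_duration, trial_index = tr$index,
    phase = tr$phase, kind = "FIXATION", reinforced = FALSE, probe = FALSE,
    stringsAsFactors = FALSE)
  if (any(tr$reinforced)) {
    rt <- tr[tr$reinforced, ]
    ev[[length(ev) + 1]] <- data.frame(
      onset = round_ms(rt$onset + cfg$us_onset_in_cs),
      duration = us_train_duration(cfg$us_n_pulses, cfg$us_pulse_duration,
                                   cfg$us_pulse_latency),
      trial_index = rt$index, phase = rt$phase, kind = "US",
      reinforced = TRUE, probe = FALSE, stringsAsFactors = FALSE)
  }
  cs_probed <- !is.na(tr$probe_onset)
  if (any(cs_probed)) {
    pt <- tr[cs_probed, ]
    ev[[length(ev) + 1]] <- data.frame(
      onset = round_ms(pt$onset + pt$probe_onset), duration = cfg$probe_duration,
      trial_index = pt$index, phase = pt$phase, kind = "PROBE",
      reinforced = FALSE, probe = TRUE, stringsAsFactors = FALSE)
  }
  iti_probed <- !is.na(tr$iti_probe_onset)
  if (any(iti_probed)) {
    pt <- tr[iti_probed, ]
    ev[[length(ev) + 1]] <- data.frame(
      onset = round_ms(pt$iti_onset + pt$iti_probe_onset),
      duration = cfg$probe_duration, trial_index = pt$index, phase = pt$phase,
      kind = "PROBE", reinforced = FALSE, probe = TRUE, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, ev)
  out <- out[order(out$onset, out$kind), ]
  rownames(out) <- NULL
  out
}

#' Total duration of a timeline in seconds
#' @param timeline an `ofl_timeline`.
#' @return end time of the last event, seconds from phase start.
#' @export
timeline_duration <- function(timeline) {
  ev <- timeline$events
  max(ev$onset + ev$duration)
}

#' @export
print.ofl_timeline <- function(x, ...) {
  tr <- x$trials
  cat(sprintf("<ofl_timeline> %s phase: %d trials (%d CS+ / %d CS-), %d reinforced,\n",
              x$phase, nrow(tr), sum(tr$cs_type == "CS_PLUS"),
              sum(tr$cs_type == "CS_MINUS"), sum(tr$reinforced)))
  cat(sprintf("  %d CS probes, %d ITI probes, duration %.1f s\n",
              sum(!is.na(tr$probe_onset)), sum(!is.na(tr$iti_probe_onset)),
              timeline_duration(x)))
  invisible(x)
}
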