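# Readers/writers for the pipeline's plain-text artifacts: recordings
# (tab-separated `time  eda  emg` plus a YAML sidecar), BIDS-style events
# tables, questionnaire answers, labels and score tables.

#' Write / read a physiological recording
#'
#' Recordings are stored as tab-separated `time  eda  emg` (seconds, uS, mV) at
#' full precision, with a YAML sidecar (same path, `.yaml` extension) carrying
#' the sampling rate, units, subject id and -- for synthetic data -- the
#' ground-truth awareness flag. A write -> read -> write cycle is
#' byte-identical.
#'
#' @param rec an `ofl_recording`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  n <- rec$n_samples
  df <- data.table::data.table(time = (seq_len(n) - 1) / rec$fs)
  if (!is.null(rec$channels$eda)) df$eda <- rec$channels$eda
  if (!is.null(rec$channels$emg)) df$emg <- rec$channels$emg
  data.table::fwrite(df, path, sep = "\t")
  meta <- list(fs = rec$fs, subject_id = rec$subject_id, role = rec$role,
               units = list(time = "s", eda = "uS", emg = "mV"),
               aware_ground_truth = if (is.na(rec$aware)) NULL else rec$aware)
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) paste0(sub("\\.tsv$", "", path), ".yaml")

#' @rdname write_recording
#' @param path recording TSV path (sidecar read from the matching `.yaml`).
#' @return `read_recording()`: an `ofl_recording`.
#' @export
read_recording <- function(path) {
  df <- data.table::fread(path, sep = "\t")
  cols <- names(df)
  stop_if_not(identical(cols[1], "time") &&
                all(cols[-1] %in% c("eda", "emg")) && length(cols) >= 2,
              "recording header must be 'time' plus 'eda'/'emg' columns")
  tm <- df$time
  stop_if_not(length(tm) >= 2, "recording too short")
  step <- diff(tm)
  bad <- which(abs(step - step[1]) > 1e-9 * max(1, abs(step[1])))
  if (length(bad))
    stop("non-monotone or gapped time column at line ", bad[1] + 2,
         call. = FALSE)
  fs <- 1 / step[1]
  meta <- if (file.exists(sidecar_path(path)))
    yaml::read_yaml(sidecar_path(path)) else list()
  if (!is.null(meta$fs) && abs(meta$fs - fs) > 1e-6 * meta$fs)
    stop(sprintf("sampling rate mismatch: sidecar says %g Hz, time column %g Hz",
                 meta$fs, fs), call. = FALSE)
  recording(fs = meta$fs %||% fs,
            eda = if ("eda" %in% cols) df$eda else NULL,
            emg = if ("emg" %in% cols) df$emg else NULL,
            subject_id = meta$subject_id %||% NA_character_,
            aware = meta$aware_ground_truth %||% NA)
}

#' Write / read an events table
#'
#' Tab-separated, BIDS-events-style: `onset duration trial_index phase kind
#' reinforced probe`, onsets/durations in seconds with 3 decimals (all event
#' times are generated on a 1 ms grid, so the format is lossless). Missing
#' trial indices (the lead-in fixation) are written as `n/a`.
#'
#' @param x an `ofl_timeline` or its `events` data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(x, path) {
  ev <- if (inherits(x, "ofl_timeline")) x$events else x
  out <- ev
  out$onset <- sprintf("%.3f", ev$onset)
  out$duration <- sprintf("%.3f", ev$duration)
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "n/a",
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @return `read_events()`: the events data.frame.
#' @export
read_events <- function(path) {
  # suppress the colClasses warning on malformed headers; the explicit header
  # check below produces the real error
  ev <- suppressWarnings(
    utils::read.table(path, sep = "\t", header = TRUE, na.strings = "n/a",
                      stringsAsFactors = FALSE,
                      colClasses = c(onset = "numeric",
                                     duration = "numeric",
                                     trial_index = "integer",
                                     phase = "character",
                                     kind = "character",
                                     reinforced = "logical",
                                     probe = "logical")))
  stop_if_not(identical(names(ev), c("onset", "duration", "trial_index",
                                     "phase", "kind", "reinforced", "probe")),
              "unexpected events header")
  ev
}

#' Write / read questionnaire answers for a cohort
#'
#' One row per subject: coded rule report, percentage ratings, forced choice
#' and the five Likert ratings.
#'
#' @param answers_list list of `ofl_answers`.
#' @param subject_ids subject identifiers.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_answers <- function(answers_list, subject_ids, path) {
  rows <- lapply(seq_along(answers_list), function(i) {
    a <- answers_list[[i]]
    data.frame(subject = subject_ids[i],
               rule_reported = a$rule_reported,
               rule_stimulus = a$rule_stimulus %||% NA_character_,
               pct_cs_plus = a$pct_ratings[["CS_PLUS"]],
               pct_cs_minus = a$pct_ratings[["CS_MINUS"]],
               pct_fixation = a$pct_ratings[["FIXATION"]],
               forced_choice = a$forced_choice,
               likert_discomfort = a$likert_ratings[["discomfort"]],
               likert_strength = a$likert_ratings[["strength"]],
               likert_naturalness = a$likert_ratings[["naturalness"]],
               likert_empathy = a$likert_ratings[["empathy"]],
               likert_identification = a$likert_ratings[["identification"]],
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     na = "n/a", row.names = FALSE)
  invisible(path)
}

#' @rdname write_answers
#' @return `read_answers()`: a named list of `ofl_answers`.
#' @export
read_answers <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, na.strings = "n/a",
                          stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    structure(list(
      rule_reported = df$rule_reported[i],
      rule_stimulus = df$rule_stimulus[i],
      pct_ratings = c(CS_PLUS = as.numeric(df$pct_cs_plus[i]),
                      CS_MINUS = as.numeric(df$pct_cs_minus[i]),
                      FIXATION = as.numeric(df$pct_fixation[i])),
      forced_choice = df$forced_choice[i],
      likert_ratings = c(discomfort = as.integer(df$likert_discomfort[i]),
                         strength = as.integer(df$likert_strength[i]),
                         naturalness = as.integer(df$likert_naturalness[i]),
                         empathy = as.integer(df$likert_empathy[i]),
                         identification = as.integer(df$likert_identification[i]))),
      class = "ofl_answers")
  })
  names(out) <- df$subject
  out
}

#' Write a cohort's artifacts to a directory
#'
#' Per subject: events tables for both phases, recordings (if rendered) with
#' sidecars, and one cohort-level answers table.
#'
#' @param cohort an `ofl_cohort`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort$subjects) {
    for (ph in names(s$timelines)) {
      write_events(s$timelines[[ph]],
                   file.path(out_dir, sprintf("%s_task-%s_events.tsv",
                                              s$subject_id, tolower(ph))))
      rec <- s$recordings[[ph]]
      if (!is.null(rec$channels$eda) || !is.null(rec$channels$emg))
        write_recording(rec, file.path(out_dir,
                                       sprintf("%s_task-%s_physio.tsv",
                                               s$subject_id, tolower(ph))))
    }
  }
  write_answers(lapply(cohort$subjects, `[[`, "answers"),
                vapply(cohort$subjects, `[[`, character(1), "subject_id"),
                file.path(out_dir, "answers.tsv"))
  invisible(out_dir)
}
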