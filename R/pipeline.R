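# End-to-end pipeline: simulate (optional) -> score SCR -> score FPS ->
# classify contingency awareness -> group-level statistics, with exclusion
# bookkeeping, mirroring the analysis set of a two-phase observational fear
# learning experiment.

#' Pipeline configuration
#'
#' @param n_subjects cohort size.
#' @param design [design_config()].
#' @param synth [synth_params()].
#' @param scr [scr_params()].
#' @param fps [fps_params()].
#' @param channels channels to simulate/score (`"eda"`, `"emg"` or both).
#' @param seed master seed.
#' @param out_dir optional output directory for report tables.
#' @return list of class `ofl_pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 35, design = design_config(),
                            synth = synth_params(), scr = scr_params(),
                            fps = fps_params(), channels = c("eda", "emg"),
                            seed = NULL, out_dir = NULL) {
  structure(list(n_subjects = n_subjects, design = design, synth = synth,
                 scr = scr, fps = fps, channels = channels, seed = seed,
                 out_dir = out_dir),
            class = "ofl_pipeline_config")
}

# Score one subject bundle (as produced by simulate_subject / read from disk).
score_one_subject <- function(sub, scr_par, fps_par, channels) {
  list(subject_id = sub$subject_id, aware = sub$aware, answers = sub$answers,
       scr = if ("eda" %in% channels)
         score_scr_subject(sub$recordings, sub$timelines, scr_par,
                           sub$subject_id),
       fps = if ("emg" %in% channels)
         score_fps_subject(sub$recordings, sub$timelines, fps_par,
                           sub$subject_id))
}

# Assemble per-subject scoring results into an ofl_scored_cohort: awareness
# labels, cohort-level noisy-recording flags, answers kept for the behavioral
# analyses.
assemble_scored <- function(per_subject, fps_par) {
  labels <- do.call(rbind, lapply(per_subject, function(s) {
    cl <- classify_contingency(s$answers)
    data.frame(subject = s$subject_id, aware = cl$aware, basis = cl$basis,
               aware_truth = s$aware, stringsAsFactors = FALSE)
  }))
  scr <- lapply(per_subject, `[[`, "scr")
  fps <- lapply(per_subject, `[[`, "fps")
  if (all(vapply(scr, is.null, logical(1)))) scr <- NULL
  if (all(vapply(fps, is.null, logical(1)))) {
    fps <- NULL
  } else {
    noisy <- flag_noisy_fps(lapply(fps, function(f) f$trials$baseline_rms),
                            fps_par)
    for (i in seq_along(fps)) {
      if (noisy[i] && !fps[[i]]$excluded) {
        fps[[i]]$excluded <- TRUE
        fps[[i]]$exclusion_reason <- "noisy"
      }
    }
  }
  structure(list(scr = scr, fps = fps, labels = labels,
                 answers = lapply(per_subject, `[[`, "answers")),
            class = "ofl_scored_cohort")
}

#' Score a simulated cohort
#'
#' Runs SCR and/or FPS scoring for every subject of a cohort and classifies
#' contingency awareness from the questionnaire answers.
#'
#' @param cohort an `ofl_cohort` from [simulate_cohort()].
#' @param scr_par [scr_params()].
#' @param fps_par [fps_params()].
#' @param channels which measures to score.
#' @return list of class `ofl_scored_cohort`: `scr` / `fps` (per-subject
#'   summaries), `labels` (data.frame subject, aware, basis, aware_truth),
#'   `answers`.
#' @export
score_cohort <- function(cohort, scr_par = scr_params(), fps_par = fps_params(),
                         channels = c("eda", "emg")) {
  assemble_scored(lapply(cohort$subjects, score_one_subject, scr_par = scr_par,
                         fps_par = fps_par, channels = channels), fps_par)
}

#' Simulate and score a cohort one subject at a time
#'
#' Equivalent to `score_cohort(simulate_cohort(...))` for the same seed, but
#' each observer's raw 2 kHz signals are discarded as soon as they are scored,
#' so memory stays flat in the cohort size. This is the path [run_pipeline()]
#' and the Monte-Carlo suites use.
#'
#' @inheritParams simulate_cohort
#' @param scr_par [scr_params()].
#' @param fps_par [fps_params()].
#' @return an `ofl_scored_cohort`, see [score_cohort()].
#' @export
simulate_scored_cohort <- function(n_subjects, cfg = design_config(),
                                   params = synth_params(),
                                   scr_par = scr_params(),
                                   fps_par = fps_params(),
                                   seed = params$seed,
                                   channels = c("eda", "emg"), aware = NULL) {
  stop_if_not(is_count(n_subjects), "'n_subjects' must be >= 1")
  channels <- match.arg(channels, several.ok = TRUE)
  seeds <- derive_seeds(seed, 7 * n_subjects + 1)
  if (is.null(aware))
    aware <- draw_awareness(n_subjects, params$p_aware,
                            seeds[[7 * n_subjects + 1]])
  per_subject <- lapply(seq_len(n_subjects), function(i) {
    sub <- simulate_subject(i, seeds[(7 * (i - 1) + 1):(7 * i)], cfg, params,
                            channels, aware[i])
    out <- score_one_subject(sub, scr_par, fps_par, channels)
    rm(sub)
    out
  })
  assemble_scored(per_subject, fps_par)
}

# Long condition-mean table for a set of subject summaries; drops subjects
# lacking any requested condition.
condition_table <- function(summaries, labels, conditions) {
  rows <- lapply(summaries, function(s) {
    v <- s$condition_means[conditions]
    if (anyNA(v)) return(NULL)
    data.frame(subject = s$subject_id, condition = conditions,
               value = as.numeric(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$group <- ifelse(labels$aware[match(out$subject, labels$subject)],
                      "aware", "unaware")
  out
}

included <- function(summaries) Filter(function(s) !s$excluded, summaries)

# both contingency groups present with >= 2 subjects each?
has_two_groups <- function(tab) {
  counts <- table(unique(tab[c("subject", "group")])$group)
  length(counts) == 2 && min(counts) >= 2
}

analyze_scr <- function(scr, labels, notes) {
  res <- list()
  inc <- included(scr)
  if (length(inc) < 3) {
    notes$push(sprintf("SCR analysis skipped: only %d subject(s) retained after exclusions",
                       length(inc)))
    return(list(results = res, notes = notes))
  }
  # observed US vs unreinforced CS+ trials (OFL phase)
  us <- condition_table(inc, labels, c("obs_US", "obs_noUS"))
  wide_us <- split(us$value, us$condition)
  res$us_vs_nous <- paired_t(wide_us$obs_US, wide_us$obs_noUS)
  res$us_vs_nous$effect <- "obs_US - obs_noUS"

  # stimulus x phase repeated-measures ANOVA on CS responses
  cs <- condition_table(inc, labels,
                        c("obs_CS_PLUS", "obs_CS_MINUS", "dir_CS_PLUS",
                          "dir_CS_MINUS"))
  cs$stimulus <- ifelse(grepl("PLUS", cs$condition), "CS_PLUS", "CS_MINUS")
  cs$phase <- ifelse(grepl("^obs", cs$condition), "OFL", "DE")
  res$rm_stimulus_phase <- rm_anova(cs, "value", c("stimulus", "phase"),
                                    "subject")

  # DE phase: stimulus x contingency-awareness mixed ANOVA + post hocs
  de <- cs[cs$phase == "DE", ]
  if (has_two_groups(de)) {
    res$mixed_de <- mixed_anova(de, "value", "stimulus", "group", "subject")
    de$cell <- de$condition
    res$posthoc_de <- bonferroni_posthoc(de, list(
      list(label = "aware: dir CS+ vs dir CS-",
           cells = c("dir_CS_PLUS", "dir_CS_MINUS"), subset_group = "aware"),
      list(label = "unaware: dir CS+ vs dir CS-",
           cells = c("dir_CS_PLUS", "dir_CS_MINUS"), subset_group = "unaware"),
      list(label = "dir CS+: aware vs unaware", cell = "dir_CS_PLUS",
           groups = c("aware", "unaware")),
      list(label = "dir CS-: aware vs unaware", cell = "dir_CS_MINUS",
           groups = c("aware", "unaware"))))
  } else {
    notes$push("SCR mixed ANOVA skipped: a contingency group has < 2 subjects")
  }
  list(results = res, notes = notes)
}

analyze_fps <- function(fps, labels, notes) {
  res <- list()
  inc <- included(fps)
  if (length(inc) < 3) {
    notes$push(sprintf("FPS analysis skipped: only %d subject(s) retained after exclusions",
                       length(inc)))
    return(list(results = res, notes = notes))
  }
  conds <- c("obs_CS_PLUS", "obs_CS_MINUS", "obs_fix",
             "dir_CS_PLUS", "dir_CS_MINUS", "dir_fix")
  tab <- condition_table(inc, labels, conds)
  tab$stimulus <- sub("^(obs|dir)_", "", tab$condition)
  tab$stimulus[tab$stimulus == "fix"] <- "FIXATION"
  tab$phase <- ifelse(grepl("^obs", tab$condition), "OFL", "DE")
  res$rm_stimulus_phase <- rm_anova(tab, "value", c("stimulus", "phase"),
                                    "subject")
  # phase post hoc: DE vs OFL subject means (unweighted across stimuli)
  pm <- tapply(tab$value, list(tab$subject, tab$phase), mean)
  res$phase_de_vs_ofl <- paired_t(pm[, "DE"], pm[, "OFL"])
  res$phase_de_vs_ofl$effect <- "DE - OFL"

  de <- tab[tab$phase == "DE", ]
  de$cell <- de$condition
  all_contrasts <- list(
    list(label = "dir CS+ vs dir fix", cells = c("dir_CS_PLUS", "dir_fix")),
    list(label = "dir CS- vs dir fix", cells = c("dir_CS_MINUS", "dir_fix")),
    list(label = "dir CS+ vs dir CS-", cells = c("dir_CS_PLUS", "dir_CS_MINUS")))
  res$posthoc_de_all <- bonferroni_posthoc(de, all_contrasts)
  if (has_two_groups(de)) {
    res$mixed_de <- mixed_anova(de, "value", "stimulus", "group", "subject")
    res$posthoc_de_aware <- bonferroni_posthoc(
      de, lapply(all_contrasts, function(ct) {
        ct$subset_group <- "aware"
        ct$label <- paste0("aware: ", ct$label)
        ct
      }))
  } else {
    notes$push("FPS mixed ANOVA skipped: a contingency group has < 2 subjects")
  }
  list(results = res, notes = notes)
}

analyze_behavior <- function(answers, labels) {
  groups <- ifelse(labels$aware, "aware", "unaware")
  summary_tab <- summarize_likert(answers, groups)
  ratings <- do.call(rbind, lapply(answers, `[[`, "likert_ratings"))
  kw <- NULL
  if (length(unique(groups)) == 2)
    kw <- do.call(rbind, lapply(colnames(ratings), function(q) {
      r <- kruskal_wallis(ratings[, q], groups)
      r$effect <- q
      r
    }))
  list(likert_summary = summary_tab, kruskal_wallis = kw)
}

#' Run the full simulate -> score -> classify -> analyze pipeline
#'
#' Every stage logs its input/output counts and exclusions; the run is
#' deterministic under the master seed. Analyses that cannot run (e.g. all
#' subjects excluded, or a contingency group with fewer than 2 members) are
#' skipped with an explicit note in the report.
#'
#' @param config [pipeline_config()].
#' @param cohort optionally, a pre-simulated `ofl_cohort` (skips simulation).
#' @return list of class `ofl_report`: `counts`, `labels`, `scr`, `fps`,
#'   `behavior`, `notes`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  notes_env <- new.env()
  notes_env$notes <- character()
  notes <- list(push = function(x) {
    notes_env$notes <- c(notes_env$notes, x)
    message(x)
  })
  if (is.null(cohort)) {
    message(sprintf("simulating %d observers (seed %s)", config$n_subjects,
                    format(config$seed %||% "none")))
    scored <- simulate_scored_cohort(config$n_subjects, config$design,
                                     config$synth, config$scr, config$fps,
                                     seed = config$seed,
                                     channels = config$channels)
  } else {
    scored <- score_cohort(cohort, config$scr, config$fps, config$channels)
  }
  labels <- scored$labels

  counts <- list(n_subjects = nrow(labels),
                 n_aware = sum(labels$aware),
                 n_unaware = sum(!labels$aware))
  message(sprintf("classified %d/%d observers as contingency-aware",
                  counts$n_aware, counts$n_subjects))

  scr_res <- fps_res <- NULL
  if (!is.null(scored$scr)) {
    counts$scr_excluded <- sum(vapply(scored$scr, `[[`, logical(1), "excluded"))
    counts$scr_analyzed <- counts$n_subjects - counts$scr_excluded
    message(sprintf("SCR: %d analyzed, %d excluded (< %d non-zero DE responses)",
                    counts$scr_analyzed, counts$scr_excluded,
                    config$scr$min_nonzero_de))
    a <- analyze_scr(scored$scr, labels, notes)
    scr_res <- a$results
  }
  if (!is.null(scored$fps)) {
    counts$fps_excluded <- sum(vapply(scored$fps, `[[`, logical(1), "excluded"))
    counts$fps_analyzed <- counts$n_subjects - counts$fps_excluded
    message(sprintf("FPS: %d analyzed, %d excluded", counts$fps_analyzed,
                    counts$fps_excluded))
    a <- analyze_fps(scored$fps, labels, notes)
    fps_res <- a$results
  }
  behavior <- analyze_behavior(scored$answers, labels)

  report <- structure(list(counts = counts, labels = labels, scr = scr_res,
                           fps = fps_res, behavior = behavior,
                           scored = scored, notes = notes_env$notes),
                      class = "ofl_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write the report tables of a pipeline run
#'
#' @param report an `ofl_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) utils::write.table(
    df, file.path(out_dir, name), sep = "\t", quote = FALSE, na = "n/a",
    row.names = FALSE)
  wt(report$labels, "labels.tsv")
  prefix_names <- function(x, prefix) {
    if (is.null(x) || !length(x)) return(list())
    setNames(x, paste0(prefix, names(x)))
  }
  stat_tables <- c(prefix_names(report$scr, "scr_"),
                   prefix_names(report$fps, "fps_"))
  if (length(stat_tables)) {
    tagged <- lapply(names(stat_tables), function(nm) {
      df <- stat_tables[[nm]]
      df$analysis <- nm
      df
    })
    all_cols <- Reduce(union, lapply(tagged, names))
    stats_df <- do.call(rbind, lapply(tagged, function(df) {
      df[setdiff(all_cols, names(df))] <- NA
      df[all_cols]
    }))
    wt(stats_df, "group_stats.tsv")
  }
  wt(report$behavior$likert_summary, "likert_summary.tsv")
  if (!is.null(report$behavior$kruskal_wallis))
    wt(report$behavior$kruskal_wallis, "likert_kruskal_wallis.tsv")
  writeLines(c(sprintf("%s: %s", names(report$counts), unlist(report$counts)),
               report$notes), file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.ofl_report <- function(x, ...) {
  cat(sprintf("<ofl_report> %d observers, %d aware / %d unaware\n",
              x$counts$n_subjects, x$counts$n_aware, x$counts$n_unaware))
  if (!is.null(x$scr))
    cat(sprintf("  SCR analyses: %s\n", paste(names(x$scr), collapse = ", ")))
  if (!is.null(x$fps))
    cat(sprintf("  FPS analyses: %s\n", paste(names(x$fps), collapse = ", ")))
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}
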