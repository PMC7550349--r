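#!/usr/bin/env Rscript
# Step 2: simulate a 35-observer cohort (the study's sample size) at the
# default generator settings, score skin conductance and startle EMG, classify
# contingency awareness, and write the subject-level tables that step 3
# analyzes. Signals are rendered and scored one observer at a time (a whole
# cohort would be gigabytes of samples); only the derived tables are kept.

library(oflphys)

seed <- 2026
n_subjects <- 35
out_dir <- file.path("results", "cohort")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cat("Simulating and scoring", n_subjects, "observers (seed", seed, ")...\n")
scored <- simulate_scored_cohort(n_subjects, design_config(), synth_params(),
                                 seed = seed)

labels <- scored$labels
write.table(labels, file.path(out_dir, "labels.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_answers(scored$answers, labels$subject,
              file.path(out_dir, "answers.tsv"))

subject_rows <- function(s, measure) {
  data.frame(subject = s$subject_id, measure = measure,
             condition = names(s$condition_means),
             value = as.numeric(s$condition_means),
             excluded = s$excluded, stringsAsFactors = FALSE)
}
cond_tab <- rbind(
  do.call(rbind, lapply(scored$scr, subject_rows, measure = "scr")),
  do.call(rbind, lapply(scored$fps, subject_rows, measure = "fps")))
write.table(cond_tab, file.path(out_dir, "condition_means.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

excl <- data.frame(
  subject = labels$subject,
  scr_excluded = vapply(scored$scr, `[[`, logical(1), "excluded"),
  scr_nonzero_de = vapply(scored$scr, `[[`, numeric(1), "n_nonzero_de"),
  fps_excluded = vapply(scored$fps, `[[`, logical(1), "excluded"),
  fps_reason = vapply(scored$fps, `[[`, character(1), "exclusion_reason"))
write.table(excl, file.path(out_dir, "exclusions.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sum(labels$aware), "of", n_subjects, "observers classified contingency-aware;",
    sum(excl$scr_excluded), "excluded from SCR and",
    sum(excl$fps_excluded), "from FPS analysis.\n")
cat("Tables written to ", out_dir, "\n", sep = "")
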