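#!/usr/bin/env Rscript
# Step 3: group-level inference on the tables written by step 2, mirroring the
# analysis set of the two-phase observational fear learning study: paired t
# (observed US vs no-US), stimulus x phase repeated-measures ANOVAs, DE-phase
# stimulus x contingency-awareness mixed ANOVAs with Bonferroni post hocs, and
# Kruskal-Wallis comparisons of the demonstrator ratings.

library(oflphys)

in_dir <- file.path("results", "cohort")
out_dir <- file.path("results", "stats")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cond <- read.table(file.path(in_dir, "condition_means.tsv"), sep = "\t",
                   header = TRUE)
labels <- read.table(file.path(in_dir, "labels.tsv"), sep = "\t", header = TRUE)
answers <- read_answers(file.path(in_dir, "answers.tsv"))
cond$group <- ifelse(labels$aware[match(cond$subject, labels$subject)],
                     "aware", "unaware")

results <- list()
say <- function(fmt, ...) cat(sprintf(fmt, ...), "\n")

## ---- skin conductance ------------------------------------------------------
scr <- cond[cond$measure == "scr" & !cond$excluded, ]
us <- reshape(scr[scr$condition %in% c("obs_US", "obs_noUS"),
                  c("subject", "condition", "value")],
              idvar = "subject", timevar = "condition", direction = "wide")
r <- paired_t(us$value.obs_US, us$value.obs_noUS)
results$scr_us_vs_nous <- r
say("SCR, observed US vs no-US: t(%d) = %.2f, p = %.2g, d = %.2f",
    r$df1, r$statistic, r$p, r$effect_size)

cs <- scr[grepl("CS", scr$condition), ]
cs$stimulus <- ifelse(grepl("PLUS", cs$condition), "CS_PLUS", "CS_MINUS")
cs$phase <- ifelse(grepl("^obs", cs$condition), "OFL", "DE")
results$scr_rm <- rm_anova(cs, "value", c("stimulus", "phase"), "subject")

de <- cs[cs$phase == "DE", ]
results$scr_mixed <- mixed_anova(de, "value", "stimulus", "group", "subject")
int <- grepl(":", results$scr_mixed$effect)
say("SCR DE phase, stimulus x contingency: F(%d, %d) = %.2f, p = %.3g, pes = %.2f",
    results$scr_mixed$df1[int], results$scr_mixed$df2[int],
    results$scr_mixed$statistic[int], results$scr_mixed$p[int],
    results$scr_mixed$effect_size[int])
de$cell <- de$condition
results$scr_posthoc <- bonferroni_posthoc(de, list(
  list(label = "aware: dir CS+ vs dir CS-",
       cells = c("dir_CS_PLUS", "dir_CS_MINUS"), subset_group = "aware"),
  list(label = "unaware: dir CS+ vs dir CS-",
       cells = c("dir_CS_PLUS", "dir_CS_MINUS"), subset_group = "unaware"),
  list(label = "dir CS+: aware vs unaware", cell = "dir_CS_PLUS",
       groups = c("aware", "unaware")),
  list(label = "dir CS-: aware vs unaware", cell = "dir_CS_MINUS",
       groups = c("aware", "unaware"))))

## ---- fear-potentiated startle ---------------------------------------------
fps <- cond[cond$measure == "fps" & !cond$excluded, ]
fps$stimulus <- sub("^(obs|dir)_", "", fps$condition)
fps$stimulus[fps$stimulus == "fix"] <- "FIXATION"
fps$phase <- ifelse(grepl("^obs", fps$condition), "OFL", "DE")
results$fps_rm <- rm_anova(fps, "value", c("stimulus", "phase"), "subject")
ph <- results$fps_rm[results$fps_rm$effect == "phase", ]
say("FPS, phase main effect: F(%d, %d) = %.2f, p = %.3g, pes = %.2f",
    ph$df1, ph$df2, ph$statistic, ph$p, ph$effect_size)

pm <- tapply(fps$value, list(fps$subject, fps$phase), mean)
r2 <- paired_t(pm[, "DE"], pm[, "OFL"])
results$fps_de_vs_ofl <- r2
say("FPS, DE vs OFL means: %.2f vs %.2f T-score units, d = %.2f",
    mean(pm[, "DE"]), mean(pm[, "OFL"]), r2$effect_size)

fde <- fps[fps$phase == "DE", ]
results$fps_mixed <- mixed_anova(fde, "value", "stimulus", "group", "subject")
fde$cell <- fde$condition
results$fps_posthoc <- bonferroni_posthoc(fde, list(
  list(label = "dir CS+ vs dir fix", cells = c("dir_CS_PLUS", "dir_fix")),
  list(label = "dir CS- vs dir fix", cells = c("dir_CS_MINUS", "dir_fix")),
  list(label = "dir CS+ vs dir CS-", cells = c("dir_CS_PLUS", "dir_CS_MINUS"))))

## ---- demonstrator ratings --------------------------------------------------
groups <- ifelse(labels$aware, "aware", "unaware")
results$likert <- summarize_likert(answers, groups)
ratings <- do.call(rbind, lapply(answers, `[[`, "likert_ratings"))
results$likert_kw <- do.call(rbind, lapply(colnames(ratings), function(q) {
  r <- kruskal_wallis(ratings[, q], groups)
  r$effect <- q
  r
}))
say("Kruskal-Wallis on the 5 rating scales: smallest p = %.2f",
    min(results$likert_kw$p))

## ---- write -----------------------------------------------------------------
for (nm in names(results)) {
  df <- results[[nm]]
  write.table(df, file.path(out_dir, paste0(nm, ".tsv")), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "n/a")
}
cat("Wrote ", length(results), " result tables to ", out_dir, "\n", sep = "")
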