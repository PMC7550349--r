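#!/usr/bin/env Rscript
# Step 1: generate one observer's experimental design (OFL + DE timelines)
# under the protocol constraints and write the BIDS-style events tables.
#
# What to look for in the output: 24/24 CS trials with 12 reinforced CS+ in
# OFL (first and last CS+ always reinforced), 12/12 and zero shocks in DE,
# probes on half the CSs (balanced over CS type and reinforcement) and a
# quarter of the ITIs, and a 0.8 s shock pulse train 7.5 s into the CS+.

library(oflphys)

seed <- 2026
out_dir <- file.path("results", "design")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- design_config()
ofl <- build_timeline(cfg, "OFL", seed = seed)
de <- build_timeline(cfg, "DE", seed = seed + 1)

write_events(ofl, file.path(out_dir, "task-ofl_events.tsv"))
write_events(de, file.path(out_dir, "task-de_events.tsv"))

summary_tab <- do.call(rbind, lapply(list(ofl, de), function(tl) {
  tr <- tl$trials
  data.frame(phase = tl$phase,
             n_cs_plus = sum(tr$cs_type == "CS_PLUS"),
             n_cs_minus = sum(tr$cs_type == "CS_MINUS"),
             n_reinforced = sum(tr$reinforced),
             n_us_events = sum(tl$events$kind == "US"),
             n_cs_probes = sum(!is.na(tr$probe_onset)),
             n_iti_probes = sum(!is.na(tr$iti_probe_onset)),
             max_run = max(rle(tr$cs_type)$lengths),
             duration_s = timeline_duration(tl))
}))
write.table(summary_tab, file.path(out_dir, "design_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Design summary (seed ", seed, "):\n", sep = "")
print(summary_tab, row.names = FALSE)
cat("\nUS pulse train spans ",
    us_train_duration(cfg$us_n_pulses, cfg$us_pulse_duration,
                      cfg$us_pulse_latency),
    " s (5 pulses, 200 ms apart).\n", sep = "")
cat("Events written to ", out_dir, "\n", sep = "")
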