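test_that("US pulse-train span matches the stimulation protocol arithmetic", {
  expect_equal(us_train_duration(5, 0.001, 0.200), 0.8)
  expect_equal(us_train_duration(1, 0.001, 0.9), 0.0)
  expect_equal(us_train_duration(3, 0.001, 0.100), 0.2)
  expect_error(us_train_duration(0, 0.001, 0.2), "positive integer")
})

test_that("CS sequences respect counts and the run-length constraint", {
  for (seed in c(1, 2, 3)) {
    s <- generate_cs_sequence(24, 24, 2, seed = seed)
    expect_length(s, 48)
    expect_equal(sum(s == "CS_PLUS"), 24)
    expect_equal(sum(s == "CS_MINUS"), 24)
    expect_lte(max(rle(s)$lengths), 2)
  }
  expect_identical(generate_cs_sequence(24, 24, 2, seed = 7),
                   generate_cs_sequence(24, 24, 2, seed = 7))
  s2 <- generate_cs_sequence(1, 1, 2, seed = 0)
  expect_setequal(s2, c("CS_PLUS", "CS_MINUS"))
  expect_error(generate_cs_sequence(3, 0, 2), "positive integer")
  expect_error(generate_cs_sequence(7, 2, 2), "infeasible")
  # asymmetric but feasible: 4 CS+ / 2 CS- with runs of 2
  s3 <- generate_cs_sequence(4, 2, 2, seed = 5)
  expect_equal(sum(s3 == "CS_PLUS"), 4)
  expect_lte(max(rle(s3)$lengths), 2)
})

test_that("every emitted 3+3 sequence lies in the exhaustively enumerated valid set", {
  valid <- enumerate_valid_sequences(3, 3, 2)
  emitted <- vapply(1:300, function(seed)
    paste(generate_cs_sequence(3, 3, 2, seed = seed), collapse = ","),
    character(1))
  expect_true(all(emitted %in% valid))
  # the sampler reaches many distinct valid orderings
  expect_gt(length(unique(emitted)), length(valid) / 2)
})

test_that("run-length property holds across many seeded sequences", {
  bad <- 0L
  for (seed in 1:2000) {
    s <- generate_cs_sequence(24, 24, 2, seed = seed)
    if (max(rle(s)$lengths) > 2 || sum(s == "CS_PLUS") != 24) bad <- bad + 1L
  }
  expect_identical(bad, 0L)
})

test_that("reinforcement selects the exact count and always the first/last CS+", {
  s <- generate_cs_sequence(24, 24, 2, seed = 11)
  plus <- which(s == "CS_PLUS")
  for (seed in 1:25) {
    r <- assign_reinforcement(s, 0.5, seed = seed)
    expect_length(r, 12)
    expect_true(all(c(plus[1], plus[24]) %in% r))
    expect_true(all(s[r] == "CS_PLUS"))
  }
  expect_identical(assign_reinforcement(rep(c("CS_PLUS", "CS_MINUS"), 2), 1.0),
                   c(1L, 3L))
  # 4 CS+ at ratio 0.5: the only valid 2-subset containing both endpoints
  s4 <- c("CS_PLUS", "CS_MINUS", "CS_PLUS", "CS_MINUS", "CS_PLUS", "CS_PLUS")
  for (seed in 1:20)
    expect_identical(assign_reinforcement(s4, 0.5, seed = seed), c(1L, 6L))
  # ties-to-even rounding: 5 CS+ at 0.5 -> round(2.5) = 2 reinforced
  s5 <- generate_cs_sequence(5, 5, 2, seed = 1)
  expect_length(assign_reinforcement(s5, 0.5, seed = 1), 2)
  expect_error(assign_reinforcement(s4, 0.25), "fewer than the 2")
})

test_that("probe placement is balanced, stratified, and uses the allowed onsets", {
  tl <- build_timeline(design_config(), "OFL", seed = 21)
  tr <- tl$trials
  probed <- !is.na(tr$probe_onset)
  expect_equal(sum(probed), 24)
  expect_equal(sum(probed & tr$cs_type == "CS_PLUS"), 12)
  expect_equal(sum(probed & tr$cs_type == "CS_MINUS"), 12)
  # stratified across reinforced / unreinforced CS+
  expect_equal(sum(probed & tr$reinforced), 6)
  expect_true(all(tr$probe_onset[probed] %in% c(6.0, 6.5, 7.0)))
  iti_probed <- !is.na(tr$iti_probe_onset)
  expect_equal(sum(iti_probed), 12)
  expect_true(all(tr$iti_probe_onset[iti_probed] >= 2.0 &
                    tr$iti_probe_onset[iti_probed] <= 4.5))
  # no CS probes requested -> none assigned
  cfg0 <- design_config(probe_cs_fraction = 0)
  tl0 <- build_timeline(cfg0, "OFL", seed = 21)
  expect_true(all(is.na(tl0$trials$probe_onset)))
})

test_that("timelines have correct composition, US placement and determinism", {
  cfg <- design_config()
  de <- build_timeline(cfg, "DE", seed = 31)
  expect_equal(sum(de$trials$cs_type == "CS_PLUS"), 12)
  expect_equal(sum(de$trials$cs_type == "CS_MINUS"), 12)
  expect_equal(sum(de$events$kind == "US"), 0)

  ofl <- build_timeline(cfg, "OFL", seed = 32)
  ev <- ofl$events
  us <- ev[ev$kind == "US", ]
  cs <- ev[ev$kind %in% c("CS_PLUS", "CS_MINUS"), ]
  parent <- cs[match(us$trial_index, cs$trial_index), ]
  expect_equal(us$onset, parent$onset + 7.5)
  expect_true(all(us$onset + us$duration <= parent$onset + parent$duration))
  expect_false(is.unsorted(ev$onset))
  expect_true(all(ofl$trials$iti_duration >= 10 & ofl$trials$iti_duration <= 15))
  expect_gte(ofl$trials$onset[1], 2)  # pre-stimulus baseline exists

  expect_identical(build_timeline(cfg, "OFL", seed = 33),
                   build_timeline(cfg, "OFL", seed = 33))
})

test_that("intertrial intervals are uniform on the configured range", {
  draws <- unlist(lapply(1:110, function(seed)
    build_timeline(design_config(), "OFL", seed = seed, probes = FALSE)$trials$iti_duration))
  expect_gte(length(draws), 5000)
  ks <- suppressWarnings(stats::ks.test(draws, "punif", 10, 15))
  expect_gt(ks$p.value, 0.01)
})

test_that("timelines round-trip losslessly through the events file", {
  tl <- build_timeline(design_config(), "OFL", seed = 41)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_events(tl, p1)
  ev <- read_events(p1)
  expect_equal(ev, tl$events, ignore_attr = TRUE)
  write_events(ev, p2)
  expect_identical(readLines(p1), readLines(p2))
})
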