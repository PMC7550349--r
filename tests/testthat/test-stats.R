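test_that("paired t handles the degenerate and hand-computed cases", {
  x <- c(1, 2, 3, 4)
  r0 <- paired_t(x, x)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  expect_equal(r0$effect_size, 0)
  # differences {1,2,3}: t = 2 / (1/sqrt(3)) = 3.4641, df = 2
  r <- paired_t(c(2, 4, 6), c(1, 2, 3))
  expect_equal(r$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(r$df1, 2)
  expect_equal(r$effect_size, 2 / 1)
  expect_error(paired_t(c(2, 3, 4), c(1, 2, 3)), "zero variance")
})

test_that("paired t agrees with an exact sign-flip permutation oracle", {
  perm_p <- function(d) {
    n <- length(d)
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    t_obs <- mean(d) / (sd(d) / sqrt(n))
    t_all <- apply(signs * rep(d, each = nrow(signs)), 1, function(z)
      mean(z) / (sd(z) / sqrt(n)))
    mean(abs(t_all) >= abs(t_obs) - 1e-12)
  }
  set.seed(42)
  for (i in 1:8) {
    x <- rnorm(9, 0.3); y <- rnorm(9)
    r <- paired_t(x, y)
    expect_lt(abs(r$p - perm_p(x - y)), 0.1)
  }
})

test_that("repeated-measures ANOVA matches a hand-worked sums-of-squares oracle", {
  # 2x2 within design, 4 subjects
  vals <- matrix(c(3, 5, 4, 8,
                   2, 4, 5, 7,
                   6, 7, 6, 11,
                   4, 6, 6, 9), nrow = 4, byrow = TRUE,
                 dimnames = list(paste0("s", 1:4),
                                 c("A.P", "A.Q", "B.P", "B.Q")))
  long <- data.frame(subject = rep(rownames(vals), each = 4),
                     stimulus = rep(c("A", "A", "B", "B"), 4),
                     phase = rep(c("P", "Q"), 8),
                     value = as.vector(t(vals)))
  res <- rm_anova(long, "value", c("stimulus", "phase"), "subject")

  # oracle: classical within-subject SS decomposition computed longhand
  n <- 4
  mean_sp <- matrix(colMeans(vals), 2, 2, byrow = TRUE,
                    dimnames = list(c("A", "B"), c("P", "Q")))
  gm <- mean(vals)
  ss_stim <- 2 * n * sum((rowMeans(mean_sp) - gm)^2)
  ss_phase <- 2 * n * sum((colMeans(mean_sp) - gm)^2)
  ss_inter <- n * sum((mean_sp - outer(rowMeans(mean_sp), colMeans(mean_sp), `+`) + gm)^2)
  subj_stim <- cbind(A = rowMeans(vals[, 1:2]), B = rowMeans(vals[, 3:4]))
  subj_phase <- cbind(P = rowMeans(vals[, c(1, 3)]), Q = rowMeans(vals[, c(2, 4)]))
  subj <- rowMeans(vals)
  ss_err_stim <- 2 * sum((subj_stim - outer(subj, rowMeans(mean_sp), `+`) + gm)^2)
  ss_err_phase <- 2 * sum((subj_phase - outer(subj, colMeans(mean_sp), `+`) + gm)^2)
  ss_total <- sum((vals - gm)^2)
  ss_subj <- 4 * sum((subj - gm)^2)
  ss_err_inter <- ss_total - ss_subj - ss_stim - ss_phase - ss_inter -
    ss_err_stim - ss_err_phase

  get <- function(e, col) res[[col]][res$effect == e]
  expect_equal(get("stimulus", "statistic"), (ss_stim / 1) / (ss_err_stim / 3),
               tolerance = 1e-9)
  expect_equal(get("phase", "statistic"), (ss_phase / 1) / (ss_err_phase / 3),
               tolerance = 1e-9)
  expect_equal(get("stimulus:phase", "statistic"),
               (ss_inter / 1) / (ss_err_inter / 3), tolerance = 1e-9)
  expect_equal(get("stimulus", "effect_size"),
               ss_stim / (ss_stim + ss_err_stim), tolerance = 1e-9)
  # internal consistency of the reported SS components
  expect_equal(res$effect_size, res$ss / (res$ss + res$ss_error),
               tolerance = 1e-12)
})

test_that("constant responses give F = 0 across the board", {
  long <- expand.grid(subject = paste0("s", 1:5),
                      stimulus = c("A", "B"), phase = c("P", "Q"))
  long$value <- 3.3
  res <- rm_anova(long, "value", c("stimulus", "phase"), "subject")
  expect_true(all(res$statistic == 0))
  expect_true(all(res$p == 1))
})

test_that("mixed ANOVA: interaction equals the difference-score t^2 and is location invariant", {
  set.seed(7)
  d <- data.frame(subject = rep(sprintf("s%02d", 1:35), each = 2),
                  group = rep(rep(c("aware", "unaware"), c(14, 21)), each = 2),
                  stimulus = rep(c("CS_PLUS", "CS_MINUS"), 35),
                  value = rnorm(70))
  d$value[d$group == "aware" & d$stimulus == "CS_PLUS"] <-
    d$value[d$group == "aware" & d$stimulus == "CS_PLUS"] + 0.8
  res <- mixed_anova(d, "value", "stimulus", "group")
  wide <- reshape(d, idvar = "subject", timevar = "stimulus",
                  direction = "wide", v.names = "value")
  diffs <- wide$value.CS_PLUS - wide$value.CS_MINUS
  tt <- t.test(diffs ~ wide$group, var.equal = TRUE)
  f_int <- res$statistic[grepl(":", res$effect)]
  expect_equal(f_int, unname(tt$statistic^2), tolerance = 1e-9)
  expect_equal(res$df2[grepl(":", res$effect)], 33)

  d2 <- d; d2$value <- d2$value + 100
  res2 <- mixed_anova(d2, "value", "stimulus", "group")
  expect_equal(res2$statistic[-1], res$statistic[-1], tolerance = 1e-9)

  d3 <- d[d$subject != "s01" | d$stimulus != "CS_PLUS", ]
  expect_error(mixed_anova(d3, "value", "stimulus", "group"), "balanced")
  d4 <- d[d$subject %in% sprintf("s%02d", 14:35), ]  # one aware subject only
  expect_error(mixed_anova(d4, "value", "stimulus", "group"), ">= 2 subjects")
})

test_that("Bonferroni post hocs scale p by the contrast count and match manual tests", {
  set.seed(8)
  d <- data.frame(subject = rep(sprintf("s%02d", 1:20), each = 2),
                  group = rep(rep(c("aware", "unaware"), each = 10), each = 2),
                  cell = rep(c("cs", "fix"), 20),
                  value = rnorm(40, rep(c(1.5, 1.0), 20)))
  one <- bonferroni_posthoc(d, list(list(label = "cs vs fix",
                                         cells = c("cs", "fix"))))
  manual <- t.test(d$value[d$cell == "cs"], d$value[d$cell == "fix"],
                   paired = TRUE)
  expect_equal(one$p, manual$p.value, tolerance = 1e-12)
  expect_identical(one$correction, "bonferroni")

  three <- bonferroni_posthoc(d, list(
    list(label = "cs vs fix", cells = c("cs", "fix")),
    list(label = "aware cs vs fix", cells = c("cs", "fix"),
         subset_group = "aware"),
    list(label = "cs: aware vs unaware", cell = "cs",
         groups = c("aware", "unaware"))))
  expect_equal(three$p[1], min(1, manual$p.value * 3), tolerance = 1e-12)
  btw <- t.test(d$value[d$cell == "cs" & d$group == "aware"],
                d$value[d$cell == "cs" & d$group == "unaware"],
                var.equal = TRUE)
  expect_equal(three$statistic[3], unname(btw$statistic), tolerance = 1e-12)
  expect_equal(three$p[3], min(1, btw$p.value * 3), tolerance = 1e-12)
  expect_error(bonferroni_posthoc(d, list(list(label = "bad",
                                               cells = c("cs", "nope")))),
               "unknown cell")
})

test_that("Kruskal-Wallis matches the hand-computed H and an exact permutation check", {
  r <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  # rank sums 6 and 15: H = 12/(6*7) * (36/3 + 225/3) - 3*7 = 3.857
  expect_equal(r$statistic, 12 / 42 * (12 + 75) - 21, tolerance = 1e-9)
  expect_equal(r$df1, 1)
  r0 <- kruskal_wallis(rep(2, 6), rep(c("a", "b"), each = 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  # exact permutation p of the H statistic vs the chi-square approximation
  x <- c(1, 5, 2, 8, 3, 9, 4, 7)
  g <- rep(c("a", "b"), 4)
  h_obs <- kruskal_wallis(x, g)$statistic
  combos <- utils::combn(8, 4)
  h_all <- apply(combos, 2, function(idx) {
    gg <- rep("b", 8); gg[idx] <- "a"
    kruskal_wallis(x, gg)$statistic
  })
  p_exact <- mean(h_all >= h_obs - 1e-12)
  expect_lt(abs(kruskal_wallis(x, g)$p - p_exact), 0.1)
})
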