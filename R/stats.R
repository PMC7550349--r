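# Group-level inference: paired t tests, repeated-measures and mixed ANOVA
# (Type III, sum-to-zero contrasts, univariate split-plot F tests via car),
# Bonferroni-corrected post-hoc contrasts, and Kruskal-Wallis for ordinal
# ratings. Effect sizes: Cohen's d (paired: mean diff / sd diff; between:
# pooled sd) and partial eta squared.

stat_result <- function(test, effect, statistic, df1, df2 = NA_real_, p,
                        effect_size = NA_real_, ci = c(NA_real_, NA_real_),
                        correction = "none", extra = NULL) {
  out <- data.frame(test = test, effect = effect, statistic = statistic,
                    df1 = df1, df2 = df2, p = p, effect_size = effect_size,
                    ci_lo = ci[1], ci_hi = ci[2], correction = correction,
                    stringsAsFactors = FALSE)
  if (!is.null(extra)) for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}

#' Two-tailed paired t test with Cohen's d
#'
#' Cohen's d is the mean of the paired differences divided by their standard
#' deviation. Identical inputs (all differences zero) return the degenerate
#' result t = 0, p = 1, d = 0; zero-variance differences with a non-zero mean
#' are an error.
#'
#' @param x,y paired per-subject values (equal length >= 2).
#' @return one-row data.frame: `test`, `effect`, `statistic` (t), `df1` (df),
#'   `p`, `effect_size` (d), `ci_lo`/`ci_hi` (95% CI of the mean difference).
#' @export
paired_t <- function(x, y) {
  stop_if_not(length(x) == length(y) && length(x) >= 2,
              "'x' and 'y' must be paired vectors of length >= 2")
  d <- x - y
  if (sd(d) == 0) {
    if (mean(d) == 0)
      return(stat_result("paired_t", "x - y", 0, length(d) - 1, NA, 1, 0,
                         c(0, 0)))
    stop("zero variance of differences with non-zero mean", call. = FALSE)
  }
  tt <- t.test(x, y, paired = TRUE)
  stat_result("paired_t", "x - y", unname(tt$statistic),
              unname(tt$parameter), NA, tt$p.value,
              mean(d) / sd(d), unname(tt$conf.int))
}

# Long table -> wide response matrix (subjects x within-cells), checking the
# design is complete and balanced (exactly one row per subject x cell).
long_to_wide <- function(data, dv, within, subject) {
  cell <- interaction(data[within], drop = FALSE, lex.order = TRUE)
  tab <- table(data[[subject]], cell)
  if (any(tab != 1))
    stop("design is not complete/balanced: expected exactly one row per ",
         "subject x cell", call. = FALSE)
  subjects <- sort(unique(data[[subject]]))
  cells <- levels(cell)
  Y <- matrix(NA_real_, length(subjects), length(cells),
              dimnames = list(subjects, cells))
  Y[cbind(match(data[[subject]], subjects), match(cell, cells))] <- data[[dv]]
  # row i of idata must describe column i of Y: derive it from the cell names
  idata <- as.data.frame(do.call(rbind, strsplit(cells, ".", fixed = TRUE)),
                         stringsAsFactors = FALSE)
  names(idata) <- within
  for (w in within) idata[[w]] <- factor(idata[[w]])
  list(Y = Y, idata = idata, subjects = subjects)
}

# Run a repeated-measures / split-plot ANOVA through car's multivariate
# machinery (Type III, sum-to-zero contrasts) and extract the univariate table.
anova_mlm <- function(Y, idata, idesign, rhs_data = NULL, rhs = ~1) {
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  dat <- if (is.null(rhs_data)) data.frame(row.names = seq_len(nrow(Y))) else
    rhs_data
  dat$.Y <- Y
  mod <- lm(stats::as.formula(paste(".Y", paste(deparse(rhs), collapse = ""))),
            data = dat)
  av <- car::Anova(mod, idata = idata, idesign = idesign, type = 3)
  # car warns when the Huynh-Feldt epsilon exceeds 1 (capped) and when the
  # error SSP matrix is singular so sphericity tests are unavailable; neither
  # affects the uncorrected univariate tests we report
  s <- withCallingHandlers(
    summary(av, multivariate = FALSE),
    warning = function(w) {
      if (grepl("HF eps|non-sphericity", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  u <- s$univariate.tests
  effects <- setdiff(rownames(u), "(Intercept)")
  res <- do.call(rbind, lapply(effects, function(e) {
    ss <- u[e, "Sum Sq"]; sse <- u[e, "Error SS"]
    fval <- u[e, "F value"]; pval <- u[e, "Pr(>F)"]
    if (!is.finite(fval) && ss <= 1e-12) { fval <- 0; pval <- 1 }
    stat_result("anova", e, fval, u[e, "num Df"], u[e, "den Df"], pval,
                effect_size = if (ss + sse > 0) ss / (ss + sse) else 0,
                extra = list(ss = ss, ss_error = sse))
  }))
  adj <- s$pval.adjustments
  res$gg_epsilon <- NA_real_; res$p_gg <- NA_real_
  if (!is.null(adj) && nrow(adj)) {
    m <- match(res$effect, rownames(adj))
    res$gg_epsilon <- ifelse(is.na(m), NA_real_, adj[m, "GG eps"])
    res$p_gg <- ifelse(is.na(m), NA_real_, adj[m, 2])
  }
  res
}

#' Repeated-measures ANOVA (within-subject factors only)
#'
#' Univariate split-plot decomposition with Type III sums of squares and
#' sum-to-zero contrasts; partial eta squared per effect
#' (`SS_effect / (SS_effect + SS_error)`). For within factors with more than
#' two levels the Greenhouse-Geisser epsilon and adjusted p are reported
#' alongside the uncorrected test.
#'
#' @param data long-format data.frame, one row per subject x cell.
#' @param dv name of the value column.
#' @param within character vector of within-subject factor column names.
#' @param subject name of the subject-identifier column.
#' @return data.frame, one row per effect (main effects and interactions):
#'   F (`statistic`), `df1`, `df2`, `p`, partial eta squared (`effect_size`),
#'   `ss`, `ss_error`, `gg_epsilon`, `p_gg`.
#' @export
rm_anova <- function(data, dv = "value", within, subject = "subject") {
  w <- long_to_wide(data, dv, within, subject)
  idesign <- stats::as.formula(paste("~", paste(within, collapse = "*")))
  res <- anova_mlm(w$Y, w$idata, idesign)
  res$test <- "rm_anova"
  res
}

#' Mixed-design ANOVA (within x between)
#'
#' Split-plot ANOVA with one or more within-subject factors and one
#' between-subject factor (e.g. stimulus type x contingency awareness), Type
#' III sums of squares, sum-to-zero contrasts, partial eta squared per effect.
#'
#' @param data long-format data.frame, one row per subject x within-cell.
#' @param dv name of the value column.
#' @param within character vector of within-subject factor column names.
#' @param between name of the between-subject factor column.
#' @param subject name of the subject-identifier column.
#' @return data.frame as in [rm_anova()].
#' @export
mixed_anova <- function(data, dv = "value", within, between,
                        subject = "subject") {
  w <- long_to_wide(data, dv, within, subject)
  grp <- data[!duplicated(data[[subject]]), c(subject, between)]
  grp <- grp[match(w$subjects, grp[[subject]]), ]
  g <- factor(grp[[between]])
  if (any(table(g) < 2))
    stop("each between-subject group needs >= 2 subjects", call. = FALSE)
  rhs_data <- data.frame(g = g)
  names(rhs_data) <- between
  idesign <- stats::as.formula(paste("~", paste(within, collapse = "*")))
  res <- anova_mlm(w$Y, w$idata, idesign, rhs_data = rhs_data,
                   rhs = stats::as.formula(paste("~", between)))
  res$test <- "mixed_anova"
  res
}

#' Bonferroni-corrected post-hoc contrasts
#'
#' Runs pairwise t tests (paired for within-subject contrasts, two-sample with
#' pooled SD for between-group contrasts), multiplies each p by the number of
#' contrasts (capped at 1), and reports Cohen's d and the uncorrected 95% CI of
#' the mean difference.
#'
#' Each contrast is a list with `label` plus either `cells = c(a, b)` (paired
#' comparison of two within-subject cells, optionally restricted via
#' `subset_group`) or `cell = a, groups = c(g1, g2)` (between-group comparison
#' of one cell).
#'
#' @param data long-format data.frame with columns `subject`, `cell`, `value`
#'   and optionally `group`.
#' @param contrasts list of contrast specifications (see Details).
#' @param dv,cell,subject,group column names.
#' @return data.frame, one row per contrast, with Bonferroni-corrected `p`.
#' @export
bonferroni_posthoc <- function(data, contrasts, dv = "value", cell = "cell",
                               subject = "subject", group = "group") {
  m <- length(contrasts)
  rows <- lapply(contrasts, function(ct) {
    dat <- data
    if (!is.null(ct$subset_group))
      dat <- dat[dat[[group]] %in% ct$subset_group, ]
    if (!is.null(ct$cells)) {
      a <- dat[dat[[cell]] == ct$cells[1], c(subject, dv)]
      b <- dat[dat[[cell]] == ct$cells[2], c(subject, dv)]
      if (!nrow(a) || !nrow(b))
        stop("unknown cell in contrast '", ct$label, "'", call. = FALSE)
      common <- intersect(a[[subject]], b[[subject]])
      r <- paired_t(a[[dv]][match(common, a[[subject]])],
                    b[[dv]][match(common, b[[subject]])])
      r$test <- "posthoc_t"
    } else {
      dat <- dat[dat[[cell]] == ct$cell, ]
      if (!nrow(dat)) stop("unknown cell in contrast '", ct$label, "'",
                           call. = FALSE)
      x <- dat[[dv]][dat[[group]] == ct$groups[1]]
      y <- dat[[dv]][dat[[group]] == ct$groups[2]]
      tt <- t.test(x, y, var.equal = TRUE)
      sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
                   (length(x) + length(y) - 2))
      r <- stat_result("posthoc_t", ct$label, unname(tt$statistic),
                       unname(tt$parameter), NA, tt$p.value,
                       (mean(x) - mean(y)) / sp, unname(tt$conf.int))
    }
    r$effect <- ct$label
    r
  })
  out <- do.call(rbind, rows)
  out$p <- pmin(1, out$p * m)
  out$correction <- "bonferroni"
  out
}

#' Kruskal-Wallis rank-sum test
#'
#' H statistic with tie correction and chi-square p value. When every
#' observation is identical the test is degenerate and H = 0, p = 1 is
#' returned.
#'
#' @param x values (ordinal ratings).
#' @param g group labels, same length as `x`.
#' @return one-row data.frame: H (`statistic`), `df1`, `p`.
#' @export
kruskal_wallis <- function(x, g) {
  g <- factor(g)
  stop_if_not(nlevels(g) >= 2, "need >= 2 groups")
  if (length(unique(x)) == 1)
    return(stat_result("kruskal_wallis", "group", 0, nlevels(g) - 1, NA, 1))
  kt <- kruskal.test(x, g)
  stat_result("kruskal_wallis", "group", unname(kt$statistic),
              unname(kt$parameter), NA, kt$p.value)
}
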