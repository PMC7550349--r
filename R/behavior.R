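# Contingency-awareness classification from post-experiment questionnaire
# answers, and Likert-rating summaries.

#' Classify contingency awareness from questionnaire answers
#'
#' An observer is contingency-aware when the forced choice names the CS+ AND
#' that choice is consistent with the earlier answers: either the open-ended
#' rule report named the CS+, or the CS+ received the (uniquely) highest shock
#' probability rating. A tied maximum does not count as "highest". Missing
#' percentage ratings with no rule report classify as unaware (basis `none`)
#' with a warning.
#'
#' @param answers an `ofl_answers` list (see [render_questionnaire()]): fields
#'   `rule_reported`, `rule_stimulus`, `pct_ratings` (named numeric:
#'   `CS_PLUS`, `CS_MINUS`, `FIXATION`), `forced_choice`.
#' @param cs_plus_identity which stimulus is the CS+.
#' @return list of class `ofl_contingency`: `aware` (flag) and `basis`
#'   (`"rule_reported_correct"`, `"pct_rating_correct"` or `"none"`).
#' @export
classify_contingency <- function(answers, cs_plus_identity = "CS_PLUS") {
  stop_if_not(!is.null(answers$forced_choice) && !is.na(answers$forced_choice),
              "'forced_choice' answer is required")
  forced_ok <- identical(answers$forced_choice, cs_plus_identity)
  rule_ok <- isTRUE(answers$rule_reported) &&
    identical(answers$rule_stimulus, cs_plus_identity)
  pct <- answers$pct_ratings
  pct_ok <- FALSE
  if (is.null(pct) || all(is.na(pct))) {
    if (!isTRUE(answers$rule_reported))
      warning("missing percentage ratings and no rule report; ",
              "classifying as unaware", call. = FALSE)
  } else {
    m <- max(pct, na.rm = TRUE)
    top <- names(pct)[!is.na(pct) & pct == m]
    pct_ok <- length(top) == 1 && identical(top, cs_plus_identity)
  }
  aware <- forced_ok && (rule_ok || pct_ok)
  basis <- if (!aware) "none" else if (rule_ok) "rule_reported_correct" else
    "pct_rating_correct"
  structure(list(aware = aware, basis = basis), class = "ofl_contingency")
}

#' Summarize Likert ratings per question, per group and overall
#'
#' Reports min, max, median and interquartile range (Q3 - Q1, linearly
#' interpolated quartiles) for each rating question, overall and within each
#' group when labels are supplied.
#'
#' @param answers_list list of `ofl_answers` (one per subject).
#' @param groups optional vector of group labels (e.g. aware/unaware), same
#'   length as `answers_list`.
#' @return data.frame with columns `question`, `group`, `n`, `min`, `max`,
#'   `median`, `iqr`.
#' @export
summarize_likert <- function(answers_list, groups = NULL) {
  ratings <- do.call(rbind, lapply(answers_list, function(a)
    a$likert_ratings))
  stop_if_not(all(ratings >= 0 & ratings <= 9), "ratings must lie in [0, 9]")
  groups <- groups %||% rep("all", nrow(ratings))
  summarize_one <- function(x, question, group) data.frame(
    question = question, group = group, n = length(x),
    min = min(x), max = max(x), median = median(x),
    iqr = unname(quantile(x, 0.75) - quantile(x, 0.25)),
    stringsAsFactors = FALSE)
  out <- list()
  for (q in colnames(ratings)) {
    out[[length(out) + 1]] <- summarize_one(ratings[, q], q, "overall")
    if (length(unique(groups)) > 1)
      for (g in unique(groups))
        out[[length(out) + 1]] <- summarize_one(ratings[groups == g, q], q,
                                                as.character(g))
  }
  do.call(rbind, out)
}
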