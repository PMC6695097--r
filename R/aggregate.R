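#' Summarize one subject-by-condition cell
#'
#' Computes keyword accuracy (pooled over keywords), the proportions of
#' sentences classified DNH-Nothing and DNH-Incorrect (out of all trials
#' of the cell), and the mean number of content-word, function-word, and
#' morpheme errors per sentence over the non-DNH trials only. Content and
#' function means pool substitutions, additions, and omissions. Means are
#' `NA` when the cell has no non-DNH trial.
#'
#' @param scores Data frame of per-trial scores (rows of [score_trials()]
#'   output) all sharing one subject and condition.
#' @return One-row data frame (a `SubjectConditionSummary`).
#' @export
summarize_subject <- function(scores) {
  if (nrow(scores) == 0L) stop("no trials to summarize")
  if (length(unique(scores$subject_id)) != 1L ||
      length(unique(scores$condition)) != 1L) {
    stop("summarize_subject expects trials of a single subject x condition")
  }
  non_dnh <- scores$dnh_status == "none"
  mean_or_na <- function(x) if (any(non_dnh)) mean(x[non_dnh]) else NA_real_
  data.frame(
    subject_id = scores$subject_id[1L],
    group = scores$group[1L],
    condition = scores$condition[1L],
    n_trials = nrow(scores),
    n_non_dnh = sum(non_dnh),
    keyword_accuracy = sum(scores$n_keywords_correct) /
      sum(scores$n_keywords),
    p_dnh_nothing = mean(scores$dnh_status == "dnh_nothing"),
    p_dnh_incorrect = mean(scores$dnh_status == "dnh_incorrect"),
    mean_content_errors = mean_or_na(scores$content_sub +
                                       scores$content_add +
                                       scores$content_om),
    mean_function_errors = mean_or_na(scores$function_sub +
                                        scores$function_add +
                                        scores$function_om),
    mean_morpheme_errors = mean_or_na(scores$morpheme_errors),
    stringsAsFactors = FALSE)
}

#' Summarize all subject-by-condition cells of a score table
#'
#' @param scores Data frame of per-trial scores from [score_trials()].
#' @return Data frame with one [summarize_subject()] row per
#'   subject-by-condition cell, ordered by group, subject, condition.
#' @export
summarize_scores <- function(scores) {
  key <- interaction(scores$subject_id, scores$condition, drop = TRUE)
  parts <- lapply(split(seq_len(nrow(scores)), key),
                  function(idx) summarize_subject(scores[idx, , drop = FALSE]))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[order(out$group, out$subject_id, out$condition), , drop = FALSE]
}

#' Per-subject masker overlap proportion
#'
#' Pools masker-overlap counts over a subject's DNH-Incorrect trials in
#' the 1T condition: matched content words / total content words. `NA`
#' when the subject has no such trial.
#'
#' @param scores Per-trial score table (may contain many subjects; only
#'   1T DNH-Incorrect rows with masker counts contribute).
#' @return Data frame with `subject_id`, `group`, `n_trials` (pooled
#'   DNH-Incorrect trials), and `overlap`.
#' @export
masker_overlap_summary <- function(scores) {
  sub <- unique(scores[, c("subject_id", "group"), drop = FALSE])
  use <- scores$condition == "1T" & scores$dnh_status == "dnh_incorrect" &
    !is.na(scores$masker_total)
  out <- do.call(rbind, lapply(seq_len(nrow(sub)), function(i) {
    rows <- use & scores$subject_id == sub$subject_id[i]
    total <- sum(scores$masker_total[rows])
    data.frame(subject_id = sub$subject_id[i], group = sub$group[i],
               n_trials = sum(rows),
               overlap = if (total > 0L)
                 sum(scores$masker_matched[rows]) / total else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Group-by-condition descriptive table
#'
#' Sample mean and sample standard deviation (n-1 denominator) of each
#' per-subject summary metric, per group-by-condition cell. Subjects with
#' a missing value for a metric are dropped from that metric's cell;
#' cells with a single subject get `NA` SD; empty cells are `NA`, never
#' zero.
#'
#' @param summaries Output of [summarize_scores()].
#' @param metrics Character vector of summary columns to describe.
#' @return Long data frame with `group`, `condition`, `metric`, `n`,
#'   `mean`, `sd`.
#' @export
group_table <- function(summaries,
                        metrics = c("keyword_accuracy", "p_dnh_nothing",
                                    "p_dnh_incorrect",
                                    "mean_content_errors",
                                    "mean_function_errors",
                                    "mean_morpheme_errors")) {
  groups <- sort(unique(summaries$group))
  conditions <- sort(unique(summaries$condition))
  grid <- expand.grid(group = groups, condition = conditions,
                      metric = metrics, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    x <- summaries[summaries$group == grid$group[i] &
                     summaries$condition == grid$condition[i],
                   grid$metric[i]]
    x <- x[!is.na(x)]
    data.frame(group = grid$group[i], condition = grid$condition[i],
               metric = grid$metric[i], n = length(x),
               mean = if (length(x)) mean(x) else NA_real_,
               sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Permutation test for a group-by-condition interaction
#'
#' Nonparametric stand-in for a mixed-model interaction contrast. For each
#' subject, the within-subject contrast is the metric in the focal
#' condition minus the mean of the metric in the remaining conditions; the
#' observed statistic is the difference of the group means of that
#' contrast. The null distribution is built by permuting group labels
#' across subjects, and the two-sided p-value uses the add-one estimator
#' p = (1 + #\{|null| >= |observed|\}) / (1 + n_perm), which cannot return
#' zero.
#'
#' @param summaries Output of [summarize_scores()] with exactly two
#'   groups and at least two conditions.
#' @param metric Name of the summary column to test.
#' @param focal_condition The condition contrasted against the mean of
#'   the others (default `"1T"`).
#' @param n_perm Number of label permutations (>= 1).
#' @param seed Optional integer seed for the permutation RNG.
#' @return List with `metric`, `statistic` (first group minus second, by
#'   sorted label), `p`, `n_perm`, `seed`, `focal_condition`,
#'   `n_subjects`.
#' @export
permutation_interaction_test <- function(summaries, metric,
                                         focal_condition = "1T",
                                         n_perm = 1000L, seed = NULL) {
  if (n_perm < 1L) stop("n_perm must be at least 1")
  if (!metric %in% names(summaries)) stop("unknown metric: ", metric)
  groups <- sort(unique(summaries$group))
  if (length(groups) != 2L) stop("exactly two groups are required")
  conditions <- unique(summaries$condition)
  if (length(conditions) < 2L) stop("at least two conditions are required")
  if (!focal_condition %in% conditions) {
    stop("focal condition '", focal_condition, "' not present")
  }

  subjects <- unique(summaries$subject_id)
  contrast <- vapply(subjects, function(s) {
    rows <- summaries[summaries$subject_id == s, , drop = FALSE]
    foc <- rows[rows$condition == focal_condition, metric]
    oth <- rows[rows$condition != focal_condition, metric]
    if (length(foc) != 1L || length(oth) < 1L) return(NA_real_)
    foc - mean(oth)
  }, 0)
  glab <- summaries$group[match(subjects, summaries$subject_id)]
  ok <- !is.na(contrast)
  if (!all(ok)) {
    warning(sum(!ok), " subject(s) dropped: metric undefined in some ",
            "condition")
    contrast <- contrast[ok]; glab <- glab[ok]
  }
  if (length(unique(glab)) != 2L) stop("a group has no usable subject")

  g1 <- glab == groups[1L]
  observed <- mean(contrast[g1]) - mean(contrast[!g1])
  n1 <- sum(g1)
  if (!is.null(seed)) set.seed(seed)
  null <- vapply(seq_len(n_perm), function(k) {
    idx <- sample.int(length(contrast), n1)
    mean(contrast[idx]) - mean(contrast[-idx])
  }, 0)
  p <- (1 + sum(abs(null) >= abs(observed))) / (1 + n_perm)
  list(metric = metric, statistic = observed, p = p,
       n_perm = as.integer(n_perm), seed = seed,
       focal_condition = focal_condition, n_subjects = length(contrast))
}
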