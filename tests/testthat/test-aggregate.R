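# build a minimal per-trial score table by hand
make_scores <- function(subject_id, condition = "1T", group = "control",
                        dnh = "none", kw = c(3L, 3L),
                        content = 0L, fun = 0L, morph = 0L) {
  n <- length(dnh)
  data.frame(subject_id = subject_id, group = group, condition = condition,
             n_keywords = rep_len(kw[1], n),
             n_keywords_correct = rep_len(kw[2], n),
             dnh_status = dnh,
             masker_matched = NA_integer_, masker_total = NA_integer_,
             content_sub = ifelse(dnh == "none", rep_len(content, n), NA),
             content_add = ifelse(dnh == "none", 0L, NA),
             content_om = ifelse(dnh == "none", 0L, NA),
             function_sub = ifelse(dnh == "none", rep_len(fun, n), NA),
             function_add = ifelse(dnh == "none", 0L, NA),
             function_om = ifelse(dnh == "none", 0L, NA),
             morpheme_errors = ifelse(dnh == "none", rep_len(morph, n), NA),
             stringsAsFactors = FALSE)
}

test_that("summarize_subject computes proportions and non-DNH means", {
  # 16 trials, 2 DNH-Nothing
  sc <- make_scores("s1", dnh = c(rep("dnh_nothing", 2), rep("none", 14)))
  su <- summarize_subject(sc)
  expect_equal(su$p_dnh_nothing, 0.125)
  expect_equal(su$p_dnh_incorrect, 0)
  expect_equal(su$n_non_dnh, 14L)

  # 16 non-DNH trials each with one function substitution
  sc <- make_scores("s1", dnh = rep("none", 16), fun = 1L)
  expect_equal(summarize_subject(sc)$mean_function_errors, 1)

  # 4 trials: 1 DNH-Incorrect, content errors 0,1,2 on the rest
  sc <- make_scores("s1", dnh = c("dnh_incorrect", rep("none", 3)),
                    content = c(0L, 0L, 1L, 2L))
  expect_equal(summarize_subject(sc)$mean_content_errors, 1)
  expect_equal(summarize_subject(sc)$p_dnh_incorrect, 0.25)

  # all trials DNH: means are missing, not zero
  sc <- make_scores("s1", dnh = rep("dnh_nothing", 4))
  expect_true(is.na(summarize_subject(sc)$mean_content_errors))

  expect_error(summarize_subject(make_scores("s1")[0, ]), "no trials")
  two <- rbind(make_scores("s1", dnh = "none"),
               make_scores("s2", dnh = "none"))
  expect_error(summarize_subject(two), "single subject")
})

test_that("summarize_subject is invariant to trial order", {
  sc <- make_scores("s1", dnh = c("dnh_incorrect", rep("none", 6),
                                  "dnh_nothing"),
                    content = c(0L, 0:5, 0L))
  set.seed(41)
  base <- summarize_subject(sc)
  for (rep in 1:5) {
    expect_equal(summarize_subject(sc[sample(nrow(sc)), ]), base)
  }
})

test_that("keyword accuracy pools keywords, not trials", {
  sc <- make_scores("s1", dnh = rep("none", 2))
  sc$n_keywords <- c(4L, 3L)
  sc$n_keywords_correct <- c(4L, 0L)
  expect_equal(summarize_subject(sc)$keyword_accuracy, 4 / 7)
})

test_that("masker overlap pools counts within subject", {
  sc <- make_scores("s1", dnh = c("dnh_incorrect", "dnh_incorrect"))
  sc$masker_matched <- c(2L, 1L)
  sc$masker_total <- c(2L, 2L)
  ov <- masker_overlap_summary(sc)
  expect_equal(ov$overlap, 0.75)

  sc$masker_matched <- c(0L, NA)
  sc$masker_total <- c(1L, NA)
  sc$dnh_status <- c("dnh_incorrect", "none")
  expect_equal(masker_overlap_summary(sc)$overlap, 0)

  # no DNH-Incorrect trials -> missing
  sc2 <- make_scores("s2", dnh = rep("none", 2))
  expect_true(is.na(masker_overlap_summary(sc2)$overlap))
})

test_that("group_table gives per-cell mean and sample SD with NA rules", {
  su <- rbind(
    data.frame(subject_id = c("a", "b"), group = "control",
               condition = "1T", n_trials = 16L, n_non_dnh = 16L,
               keyword_accuracy = c(0.6, 0.8), p_dnh_nothing = 0,
               p_dnh_incorrect = 0, mean_content_errors = 0,
               mean_function_errors = 0, mean_morpheme_errors = 0),
    data.frame(subject_id = "c", group = "MDD", condition = "1T",
               n_trials = 16L, n_non_dnh = 0L, keyword_accuracy = 0.5,
               p_dnh_nothing = 0.5, p_dnh_incorrect = 0.5,
               mean_content_errors = NA_real_,
               mean_function_errors = NA_real_,
               mean_morpheme_errors = NA_real_))
  gt <- group_table(su)
  cell <- gt[gt$group == "control" & gt$metric == "keyword_accuracy", ]
  expect_equal(cell$mean, 0.7)
  expect_equal(cell$sd, sqrt(0.02), tolerance = 1e-12)
  # n = 1 cell: SD missing
  cell <- gt[gt$group == "MDD" & gt$metric == "keyword_accuracy", ]
  expect_true(is.na(cell$sd))
  expect_equal(cell$n, 1L)
  # metric missing for every subject of a cell: mean missing, not zero
  cell <- gt[gt$group == "MDD" & gt$metric == "mean_content_errors", ]
  expect_equal(cell$n, 0L)
  expect_true(is.na(cell$mean))
  # identical subjects: SD zero
  su2 <- su[c(1, 1), ]
  su2$subject_id <- c("a", "b")
  gt2 <- group_table(su2)
  expect_equal(gt2$sd[gt2$metric == "keyword_accuracy" &
                        gt2$group == "control"], 0)
})

# synthetic summaries for the permutation test: two groups x three
# conditions, optionally with a focal-condition group effect
perm_summaries <- function(n_per_group, effect_1t = 0, sd = 0.05,
                           seed = 1) {
  set.seed(seed)
  grid <- expand.grid(subject_id = seq_len(2 * n_per_group),
                      condition = c("1T", "1T_tr", "SSN"),
                      stringsAsFactors = FALSE)
  grid$group <- ifelse(grid$subject_id <= n_per_group, "MDD", "control")
  grid$subject_id <- sprintf("s%03d", grid$subject_id)
  mu <- 0.5 + ifelse(grid$condition == "1T" & grid$group == "MDD",
                     effect_1t, 0)
  grid$keyword_accuracy <- stats::rnorm(nrow(grid), mu, sd)
  grid
}

test_that("permutation test is calibrated and detects planted effects", {
  # identical groups: large p
  su <- perm_summaries(20, effect_1t = 0, seed = 42)
  res <- permutation_interaction_test(su, "keyword_accuracy",
                                      n_perm = 1000, seed = 1)
  expect_gt(res$p, 0.05)

  # planted 10-point focal-condition deficit, within-group SD 5 points
  su <- perm_summaries(20, effect_1t = -0.10, sd = 0.05, seed = 43)
  res <- permutation_interaction_test(su, "keyword_accuracy",
                                      n_perm = 1000, seed = 1)
  expect_lt(res$p, 0.05)
  expect_equal(res$n_subjects, 40L)
})

test_that("permutation p-values are seed-reproducible and add-one bounded", {
  su <- perm_summaries(10, effect_1t = -0.3, sd = 0.02, seed = 44)
  r1 <- permutation_interaction_test(su, "keyword_accuracy",
                                     n_perm = 2000, seed = 7)
  r2 <- permutation_interaction_test(su, "keyword_accuracy",
                                     n_perm = 2000, seed = 7)
  expect_identical(r1$p, r2$p)
  # an overwhelming effect pins p at the add-one floor for any seed
  r3 <- permutation_interaction_test(su, "keyword_accuracy",
                                     n_perm = 2000, seed = 8)
  expect_equal(r1$p, 1 / 2001)
  expect_equal(r3$p, 1 / 2001)

  expect_error(permutation_interaction_test(su, "keyword_accuracy",
                                            n_perm = 0), "n_perm")
  expect_error(permutation_interaction_test(su, "nope"), "unknown metric")
})

test_that("permutation rejection rate is near nominal under the null", {
  # 120 null datasets scored at alpha = 0.05 (fast surrogate summaries)
  rejections <- 0L
  for (k in 1:120) {
    su <- perm_summaries(12, effect_1t = 0, seed = 500 + k)
    res <- permutation_interaction_test(su, "keyword_accuracy",
                                        n_perm = 200, seed = k)
    rejections <- rejections + (res$p <= 0.05)
  }
  rate <- rejections / 120
  expect_gte(rate, 0.005)
  expect_lte(rate, 0.12)
})
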