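test_that("confusion counts match hand enumeration", {
  all_pos <- confusion(rep(TRUE, 5), rep(TRUE, 5))
  expect_equal(unlist(all_pos[c("tp", "fp", "tn", "fn")]),
               c(tp = 5L, fp = 0L, tn = 0L, fn = 0L))

  flipped <- confusion(c(TRUE, FALSE, TRUE), c(FALSE, TRUE, FALSE))
  expect_equal(flipped$tp, 0L)
  expect_equal(flipped$tn, 0L)

  pred <- c(T, T, F, F, T, F, T, F, F, T)
  lab  <- c(T, F, F, T, T, F, F, F, T, T)
  cm <- confusion(pred, lab)
  expect_equal(unlist(cm[c("tp", "fp", "tn", "fn")]),
               c(tp = 3L, fp = 2L, tn = 3L, fn = 2L))
  expect_error(confusion(c(TRUE), c(TRUE, FALSE)), "length")
})

test_that("point metrics follow the imbalance-aware formulas", {
  # sens/spec pairs from a published model-comparison table reproduce the
  # printed G-means at 2 dp
  rows <- list(c(0.83, 0.57, 0.69), c(0.70, 0.80, 0.75),
               c(0.60, 0.88, 0.73), c(0.24, 0.94, 0.47),
               c(0.42, 0.88, 0.61), c(0.34, 0.94, 0.57),
               c(0.37, 0.88, 0.57), c(0.61, 0.79, 0.69))
  for (r in rows) expect_equal(round(sqrt(r[1] * r[2]), 2), r[3])

  zero_tp <- metrics_from_confusion(confusion_counts(0, 3, 90, 7))
  expect_equal(zero_tp$f_score, 0)
  expect_equal(zero_tp$sensitivity, 0)

  no_pred_pos <- metrics_from_confusion(confusion_counts(0, 0, 95, 5))
  expect_equal(no_pred_pos$precision, 0)
  expect_equal(no_pred_pos$f_score, 0)
  expect_equal(no_pred_pos$specificity, 1)

  cm <- metrics_from_confusion(confusion_counts(30, 20, 700, 19))
  expect_equal(cm$sensitivity, 30 / 49)
  expect_equal(cm$specificity, 700 / 720)
  expect_equal(cm$precision, 30 / 50)
  expect_equal(cm$f_score, 2 * (30 / 50) * (30 / 49) / (30 / 50 + 30 / 49))
  expect_equal(cm$g_mean, sqrt((30 / 49) * (700 / 720)))
})

test_that("AUC equals brute-force pairwise concordance, robust to ties", {
  perfect <- auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(perfect, 1.0)
  expect_equal(auc(rep(1, 10), rep(c(TRUE, FALSE), 5)), 0.5)

  set.seed(51)
  for (rep in 1:6) {
    lab <- runif(50) < 0.3
    if (!any(lab)) lab[1] <- TRUE
    if (all(lab)) lab[2] <- FALSE
    scores <- round(rnorm(50) + lab, 1)  # rounding forces ties
    expect_equal(auc(scores, lab), oracle_auc(scores, lab),
                 tolerance = 1e-12)
    # invariance under a strictly increasing transform
    expect_equal(auc(exp(scores), lab), auc(scores, lab), tolerance = 1e-12)
  }

  expect_error(roc_curve(1:5, rep(TRUE, 5)), "both classes")
})

test_that("AUC cross-checks against an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(52)
  lab <- runif(80) < 0.4
  lab[1:2] <- c(TRUE, FALSE)
  scores <- round(rnorm(80) + 0.8 * lab, 1)
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(lab, scores,
                                                         quiet = TRUE))))
  expect_equal(auc(scores, lab), ref, tolerance = 1e-10)
})

test_that("optimal ROC point maximizes Youden's J with specificity tie-break", {
  curve <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  pt <- optimal_roc_point(curve)
  expect_equal(pt$j, 1.0)
  expect_equal(pt$sensitivity, 1.0)
  expect_equal(pt$specificity, 1.0)

  flat <- optimal_roc_point(roc_curve(rep(1, 10), rep(c(TRUE, FALSE), 5)))
  expect_equal(flat$j, 0)
  expect_equal(flat$specificity, 1)  # tie broken toward the stricter vertex

  set.seed(53)
  scores <- sample(1:5, 30, TRUE)
  lab <- runif(30) < scores / 6
  lab[1:2] <- c(TRUE, FALSE)
  curve <- roc_curve(scores, lab)
  pt <- optimal_roc_point(curve)
  j_all <- curve$tpr - curve$fpr
  expect_equal(pt$j, max(j_all))
  cm <- metrics_from_confusion(pt$counts)
  expect_equal(cm$sensitivity, pt$sensitivity)
  expect_equal(cm$specificity, pt$specificity)
})

test_that("pattern and score evaluation share the same metric panel", {
  tab <- toy_cohort(n = 80, seed = 101)
  always <- pattern("aki", list(condition("age", ">", -999)), 1L)
  r <- evaluate_pattern(always, tab)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 0)

  never <- pattern("aki", list(condition("age", "<=", -999),
                               condition("lvef", ">", 999)), 2L)
  r0 <- evaluate_pattern(never, tab)
  expect_equal(r0$counts$tp, 0L)
  expect_equal(r0$f_score, 0)

  # labels as their own scores are a perfect classifier
  lab <- cohort_labels(tab)
  rs <- evaluate_scores(as.numeric(lab), lab, cutoff = 0.5)
  expect_equal(rs$sensitivity, 1)
  expect_equal(rs$specificity, 1)
  expect_equal(rs$auc, 1)
  expect_equal(rs$f_score, 1)

  # cutoff "optimal" is definitionally the optimal ROC point
  set.seed(54)
  scores <- rnorm(80) + lab
  ro <- evaluate_scores(scores, lab, cutoff = "optimal")
  pt <- optimal_roc_point(roc_curve(scores, lab))
  expect_equal(ro$sensitivity, pt$sensitivity)
  expect_equal(ro$specificity, pt$specificity)
  expect_equal(ro$threshold, pt$cutoff)

  # 12-patient toy score table against a hand-computed confusion
  s12 <- c(8, 3, 9, 1, 7, 2, 6, 5, 10, 4, 8, 2)
  l12 <- c(T, F, T, F, T, F, F, T, T, F, F, F)
  r12 <- evaluate_scores(s12, l12, cutoff = 6)
  expect_equal(unlist(r12$counts[c("tp", "fp", "tn", "fn")]),
               c(tp = 4L, fp = 2L, tn = 5L, fn = 1L))
})

test_that("cohort comparison mirrors a baseline table", {
  set.seed(55)
  n1 <- 120; n2 <- 60
  mk <- function(n, age_mu, p_yes, p_out) {
    data.frame(age = rnorm(n, age_mu, 10),
               anemia = sample(c("Yes", "No"), n, TRUE, c(p_yes, 1 - p_yes)),
               out = runif(n) < p_out, stringsAsFactors = FALSE)
  }
  sch <- cohort_schema(variable_spec("age", "numeric", units = "years"),
                       variable_spec("anemia", "binary",
                                     positive_category = "Yes"))
  tr <- cohort(mk(n1, 64, 0.1, 0.08), sch, "out")
  te <- cohort(mk(n2, 64, 0.1, 0.08), sch, "out")
  res <- compare_cohorts(tr, te)
  expect_equal(res$variable, c("age", "anemia", "out"))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))

  # numeric row equals the two-group equal-variance ANOVA p-value
  ref <- stats::oneway.test(
    c(tr$data$age, te$data$age) ~ rep(c("a", "b"), c(n1, n2)),
    var.equal = TRUE)
  expect_equal(res$p_value[res$variable == "age"], ref$p.value)

  # identical groups: chi-square statistic 0, p = 1
  same <- compare_cohorts(tr, tr)
  cat_rows <- same[same$kind != "numeric", ]
  expect_true(all(cat_rows$statistic == 0))
  expect_true(all(cat_rows$p_value == 1))
})

test_that("report_table lays out one model per row", {
  tab <- toy_cohort(n = 60, seed = 107)
  reports <- list(
    pre = evaluate_pattern(pattern("aki",
                                   list(condition("lvef", "<=", 55)), 1L),
                           tab),
    scores = evaluate_scores(as.numeric(tab$data$lvef < 55),
                             cohort_labels(tab), cutoff = 0.5))
  out <- report_table(reports)
  expect_equal(out$model, c("pre", "scores"))
  expect_equal(names(out), c("model", "auc", "sensitivity", "specificity",
                             "f_score", "g_mean"))
})
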