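test_that("roc_auc matches worked examples and pairwise enumeration", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.6), c(1, 1, 0, 0)), 1.0)
  # 4 positive-negative pairs, one tie counted 1/2
  expect_equal(roc_auc(c(0.2, 0.8, 0.8, 0.5), c(0, 1, 0, 1)), 0.625)
  # property: rank form == brute-force pair counting, with heavy ties
  set.seed(10)
  for (i in 1:30) {
    n <- sample(4:50, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.4))  # both classes guaranteed
    expect_equal(roc_auc(scores, labels), pairwise_auc(scores, labels))
    # sign reversal flips the AUC
    expect_equal(roc_auc(-scores, labels), 1 - roc_auc(scores, labels))
    # invariance under strictly increasing transform
    expect_equal(roc_auc(exp(3 * scores), labels), roc_auc(scores, labels))
  }
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "both classes")
  # independent cross-check against the trapezoidal ROC implementation
  set.seed(12)
  s <- runif(80); y <- c(0, 1, rbinom(78, 1, 0.3))
  expect_equal(roc_auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))))
})

test_that("confusion metrics count the >=-threshold confusion matrix", {
  # 2 TP, 1 FN, 3 TN, 1 FP
  scores <- c(0.9, 0.8, 0.2, 0.1, 0.15, 0.3, 0.7)
  labels <- c(1, 1, 1, 0, 0, 0, 0)
  m <- confusion_metrics(scores, labels, 0.5)
  expect_equal(unname(m), c(2 / 3, 3 / 4, 5 / 7))
  # degenerate thresholds
  expect_equal(unname(confusion_metrics(scores, labels, 0)[1:2]), c(1, 0))
  expect_equal(unname(confusion_metrics(scores, labels, 2)[1:2]), c(0, 1))
})

test_that("threshold optimization maximizes the weighted criterion exactly", {
  scores <- c(0.1, 0.35, 0.4, 0.8); labels <- c(0, 1, 0, 1)
  r <- optimize_threshold(scores, labels, u = 2 / 3)
  expect_equal(r$threshold, 0.35)
  expect_equal(r$sensitivity, 1.0)
  expect_equal(r$specificity, 0.5)
  expect_equal(2 / 3 * r$sensitivity + 1 / 3 * r$specificity, 5 / 6)
  # u = 1: sensitivity-only limit picks the minimum score
  expect_equal(optimize_threshold(scores, labels, u = 1)$threshold, min(scores))
  expect_equal(optimize_threshold(scores, labels, u = 1)$sensitivity, 1)
  # u = 0: specificity is maximal over the candidate grid
  r0 <- optimize_threshold(scores, labels, u = 0)
  best_spec <- max(vapply(unique(scores), function(t)
    confusion_metrics(scores, labels, t)[["specificity"]], numeric(1)))
  expect_equal(r0$specificity, best_spec)
  # oracle: exhaustive candidate search on random instances, ties to lower t
  set.seed(21)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    s <- round(runif(n), 2)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    u <- runif(1)
    r <- optimize_threshold(s, y, u)
    cand <- sort(unique(s))
    obj <- vapply(cand, function(t) {
      m <- confusion_metrics(s, y, t)
      u * m[["sensitivity"]] + (1 - u) * m[["specificity"]]
    }, numeric(1))
    expect_equal(u * r$sensitivity + (1 - u) * r$specificity, max(obj))
    expect_equal(r$threshold, cand[which(obj >= max(obj) - 1e-12)[1]])
  }
  expect_error(optimize_threshold(scores, labels, u = 1.2), "0,1")
})

test_that("subgroup AUCs restrict the rank statistic to each subgroup", {
  set.seed(3)
  n <- 60
  scores <- runif(n); labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
  g <- rep(c("a", "b"), each = n / 2)
  sub <- subgroup_auc(scores, labels, g)
  for (s in c("a", "b")) {
    idx <- g == s
    expect_equal(sub[[s]], pairwise_auc(scores[idx], labels[idx]))
  }
  # two identical subgroups share the overall AUC
  s2 <- c(scores, scores); y2 <- c(labels, labels)
  g2 <- rep(c("u", "v"), each = n)
  sub2 <- subgroup_auc(s2, y2, g2)
  expect_equal(unname(sub2["u"]), roc_auc(s2, y2))
  expect_equal(unname(sub2["v"]), roc_auc(s2, y2))
  # single-class subgroup flagged NA with a warning, not dropped silently
  g3 <- g
  g3[which(labels == 1 & g == "a")[1:3]] <- "c"  # "c" holds positives only
  expect_warning(sub3 <- subgroup_auc(scores, labels, g3), "single outcome class")
  expect_true(is.na(sub3[["c"]]))
})

test_that("RPPS reproduces every printed model/outcome/attribute cell to 3 dp", {
  battery <- published_rpps_battery()
  for (i in seq_len(nrow(battery))) {
    got <- rpps(battery$overall[i], c(battery$sub1[i], battery$sub2[i]))
    expect_equal(round(got, 3), battery$rpps[i],
                 info = paste(battery$outcome[i], battery$model[i],
                              battery$attribute[i]))
  }
})

test_that("RPPS semantics: bound at 1, no clamping below, errors", {
  expect_equal(rpps(0.7, c(a = 0.7, b = 0.7)), 1)
  # deviation larger than the overall AUC makes RPPS negative
  expect_lt(rpps(0.4, c(a = 0.9)), 0)
  set.seed(8)
  for (i in 1:20) {
    overall <- runif(1, 0.4, 0.9)
    subs <- runif(3, 0.3, 1)
    r <- rpps(overall, subs)
    expect_lte(r, 1)
    if (max(abs(subs - overall)) > 0) expect_lt(r, 1)
  }
  expect_error(rpps(0, c(a = 0.5)), "positive")
  expect_error(rpps(0.5, numeric(0)), "no evaluable")
  expect_warning(r <- rpps(0.6, c(a = 0.6, b = NA)), "unevaluable")
  expect_equal(r, 1)
})

test_that("assess_model composes metrics and fairness over the test set", {
  # exchangeable groups and a model blind to them: RPPS near 1 at large n
  spec <- small_spec(n = 6000, seed = 13, coef_mi = c(x1 = 1.5), intercept = -1)
  tab <- generate_cohort(spec)
  x <- encode_one_hot(tab)
  sp <- split_train_test(nrow(x), 0.7, seed = 2)
  m <- risk_model(x[sp$train, c("x1", "x2")], tab$y[sp$train], "glmnet",
                  grid = list(alpha = 0, lambda = 0.001))
  a <- assess_model(m, x[sp$test, c("x1", "x2")], tab$y[sp$test],
                    protected = list(grp = tab$grp[sp$test],
                                     coin = rep(c("h", "t"),
                                                length.out = length(sp$test))))
  expect_gt(a$fairness$grp$rpps, 0.9)
  # two protected attributes -> two independent fairness reports
  expect_equal(names(a$fairness), c("grp", "coin"))
  expect_equal(a$fairness$grp$overall_auc, a$fairness$coin$overall_auc)
  # model AUC close to the AUC of the true generating probabilities
  truth_scores <- plogis(-1 + 1.5 * tab$x1[sp$test])
  expect_lt(abs(a$performance$auc - roc_auc(truth_scores, tab$y[sp$test])), 0.02)
  # tabulation has the report shape: metrics + per-subgroup AUC + RPPS
  tab_out <- assessment_table(list(glmnet = a))
  expect_true(all(c("model", "auc", "sensitivity", "specificity", "accuracy",
                    "auc_grp_a", "auc_grp_b", "rpps_grp", "rpps_coin") %in%
                    names(tab_out)))
})
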