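test_that("bootstrapped permutation importance: null, signal and determinism", {
  # binary feature equal to the outcome + a constant and a noise column
  set.seed(2)
  n <- 120
  y <- rbinom(n, 1, 0.5)
  x <- cbind(signal = y, constant = rep(1, n), noise = rnorm(n))
  fit_fun <- function(x, y, seed = 1) {
    risk_model(x, y, "cart", grid = list(maxdepth = 2, cp = 0, minbucket = 1),
               seed = seed)
  }
  cfg <- explain_config(n_bootstrap = 25, seed = 5)
  imp <- bootstrap_permutation_importance(fit_fun, x, y, cfg)
  # permuting a constant column is the identity: importance exactly 0
  expect_equal(imp$mean[imp$feature == "constant"], 0)
  # perfect predictor: baseline AUC 1, permuted ~ 0.5, drop ~ 0.5
  expect_lt(abs(imp$mean[imp$feature == "signal"] - 0.5), 0.1)
  expect_equal(imp$rank[imp$feature == "signal"], 1L)
  expect_true(all(imp$lower <= imp$upper))
  expect_true(all(sort(imp$rank) == 1:3))
  # deterministic given seed
  imp2 <- bootstrap_permutation_importance(fit_fun, x, y, cfg)
  expect_identical(as.data.frame(imp), as.data.frame(imp2))
})

test_that("exact linear Shapley values satisfy the closed form and efficiency", {
  x <- matrix(c(1, 1), 1, 2, dimnames = list(NULL, c("f1", "f2")))
  bg <- matrix(0, 4, 2, dimnames = list(NULL, c("f1", "f2")))
  s <- shapley_linear_exact(c(f1 = 1, f2 = -2), 0, x, bg)
  expect_equal(unname(s$values[1, ]), c(1, -2))
  expect_equal(s$base, 0)
  expect_equal(unname(rowSums(s$values) + s$base), unname(s$margin))
  expect_equal(s$margin, -1)
  # row at the background mean gets zero attribution
  s0 <- shapley_linear_exact(c(f1 = 1, f2 = -2), 3, bg[1, , drop = FALSE], bg)
  expect_equal(unname(s0$values[1, ]), c(0, 0))
  # doubling the coefficients doubles the values
  s2 <- shapley_linear_exact(c(f1 = 2, f2 = -4), 0, x, bg)
  expect_equal(s2$values, 2 * s$values)
  expect_error(shapley_linear_exact(c(f1 = 1, f2 = 1), 0, x, bg[0, ]), "empty")
})

test_that("sampling Shapley agrees with the exact linear method and enumeration", {
  spec <- small_spec(n = 300, seed = 6, coef_mi = c(x1 = 1, x2 = -0.8),
                     intercept = -0.3)
  tab <- generate_cohort(spec)
  x <- encode_one_hot(tab)
  m <- risk_model(x, tab$y, "glmnet", grid = list(alpha = 0, lambda = 1e-4))
  bg <- x[1:40, ]
  rows <- x[41:45, ]
  ss <- shapley_sampling(m, rows, bg, explain_config(shapley_samples = 6, seed = 3))
  b <- coef(m)
  le <- shapley_linear_exact(b[-1], b[["(Intercept)"]], rows, bg)
  # linear margin: every ordering credits identically, so agreement is exact
  expect_equal(ss$values, le$values, tolerance = 1e-8)
  expect_equal(ss$base, le$base, tolerance = 1e-8)

  # nonlinear 2-feature model: brute-force over both orderings and all
  # background rows must reproduce the exhaustive estimator exactly
  x2 <- x[, c("x1", "x2")]
  mt <- risk_model(x2, tab$y, "cart", grid = list(maxdepth = 2, cp = 0.01))
  bg2 <- x2[1:15, ]; r2 <- x2[16:18, ]
  ss2 <- shapley_sampling(mt, r2, bg2, explain_config(shapley_samples = 2, seed = 1))
  f <- function(mm) mean(margin_scores(mt, mm))
  for (i in 1:3) {
    sub <- function(cols) {
      mmat <- bg2
      if (length(cols) > 0) {
        mmat[, cols] <- matrix(r2[i, cols], nrow(bg2), length(cols), byrow = TRUE)
      }
      f(mmat)
    }
    phi1 <- 0.5 * ((sub("x1") - sub(character(0))) +
                     (sub(c("x1", "x2")) - sub("x2")))
    phi2 <- 0.5 * ((sub("x2") - sub(character(0))) +
                     (sub(c("x1", "x2")) - sub("x1")))
    expect_equal(unname(ss2$values[i, ]), c(phi1, phi2), tolerance = 1e-10)
  }
  # efficiency: base + sum of values = per-row margin
  expect_equal(unname(rowSums(ss2$values) + ss2$base),
               unname(margin_scores(mt, r2)), tolerance = 1e-10)
})

test_that("relative Shapley normalizes by the row total attribution", {
  x <- matrix(c(0.5, 2), 2, 1, dimnames = list(NULL, "only"))
  bg <- matrix(0, 3, 1, dimnames = list(NULL, "only"))
  s1 <- shapley_linear_exact(c(only = 2), 0, x, bg)
  r1 <- relative_shapley(s1)
  # single feature: every row's relative value is 1
  expect_equal(unname(r1$values[, 1]), c(1, 1))
  # arithmetic: (0.3, 0.1) over total 0.4 -> (0.75, 0.25)
  fake <- structure(list(values = matrix(c(0.3, 0.1), 1, 2,
                                         dimnames = list(NULL, c("a", "b"))),
                         base = 0, margin = 0.4, scale = "margin"),
                    class = "shap_matrix")
  expect_equal(unname(relative_shapley(fake)$values[1, ]), c(0.75, 0.25))
  # sign preserved when the total is positive
  fake2 <- structure(list(values = matrix(c(0.5, -0.1), 1, 2,
                                          dimnames = list(NULL, c("a", "b"))),
                          base = 0, margin = 0.4, scale = "margin"),
                     class = "shap_matrix")
  expect_equal(unname(relative_shapley(fake2)$values[1, ]), c(1.25, -0.25))
  # degenerate rows flagged and excluded from the means
  fake3 <- structure(list(values = matrix(c(0.3, 0.3, 0.1, -0.3), 2, 2,
                                          dimnames = list(NULL, c("a", "b"))),
                          base = 0, margin = c(0, 0), scale = "margin"),
                     class = "shap_matrix")
  r3 <- relative_shapley(fake3)
  expect_equal(r3$degenerate, c(FALSE, TRUE))
  expect_true(all(is.na(r3$values[2, ])))
  fake4 <- fake3; fake4$values[] <- 0
  expect_error(relative_shapley(fake4), "zero total")
})

test_that("partial dependence recovers logistic slopes and handles indicators", {
  spec <- small_spec(n = 400, seed = 8, coef_mi = c(x1 = 0.9, "grp=b" = 0.6),
                     intercept = -0.5)
  tab <- generate_cohort(spec)
  x <- encode_one_hot(tab)
  m <- risk_model(x, tab$y, "glmnet", grid = list(alpha = 0, lambda = 1e-4))
  b <- coef(m)
  pd <- partial_dependence(m, x, "x1")
  # log-odds PDP of a linear-margin model is affine in v with slope beta
  slopes <- diff(pd$curve$mean_logodds) / diff(pd$curve$value)
  expect_lt(max(abs(slopes - b[["x1"]])), 1e-9)
  expect_equal(nrow(pd$curve), 50)
  expect_true(all(pd$curve$mean_risk >= 0 & pd$curve$mean_risk <= 1))
  # binary indicator gets exactly its two observed grid points
  pdb <- partial_dependence(m, x, "grp=b")
  expect_equal(pdb$curve$value, c(0, 1))
  expect_equal(diff(pdb$curve$mean_logodds), b[["grp=b"]], tolerance = 1e-9)
  # a feature the model ignores yields a flat curve at the mean output
  x3 <- cbind(x, dead = rnorm(nrow(x)))
  m3 <- risk_model(x3, tab$y, "glmnet", grid = list(alpha = 1, lambda = 0.05))
  if (coef(m3)[["dead"]] == 0) {
    pd3 <- partial_dependence(m3, x3, "dead")
    expect_lt(diff(range(pd3$curve$mean_logodds)), 1e-12)
    expect_equal(pd3$curve$mean_risk[1], mean(risk_scores(m3, x3)), tolerance = 1e-12)
  }
  expect_error(partial_dependence(m, x, "nope"), "unknown feature")
})

test_that("integrated explanation ranks a dominant feature first everywhere", {
  spec <- small_spec(n = 500, seed = 15,
                     coef_mi = c(x1 = 2.0, x2 = 0.1), intercept = -0.5)
  tab <- generate_cohort(spec)
  x <- encode_one_hot(tab)
  m <- risk_model(x, tab$y, "glmnet", grid = list(alpha = 0, lambda = 1e-3))
  cfg <- explain_config(n_bootstrap = 20, top_k = 2, background_samples = 50,
                        seed = 4)
  ex <- explain_model(m, x, tab$y, cfg)
  expect_equal(ex$importance$feature[ex$importance$rank == 1], "x1")
  expect_equal(ex$top_features[1], "x1")
  means <- colMeans(abs(ex$shapley$values))
  expect_equal(names(which.max(means)), "x1")
  expect_equal(names(ex$pdp), ex$top_features)
  expect_length(ex$pdp, 2)
  # steepest PDP slope belongs to the dominant feature
  slope_of <- function(p) abs(coef(lm(mean_logodds ~ value, p$curve))[2])
  expect_gt(slope_of(ex$pdp$x1), 0.5)
  # top_k larger than the feature count clamps to all features
  cfg_all <- explain_config(n_bootstrap = 5, top_k = 99, seed = 4)
  ex2 <- explain_model(m, x, tab$y, cfg_all)
  expect_length(ex2$pdp, ncol(x))
})
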