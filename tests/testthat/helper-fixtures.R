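# shared fixtures: small cohort specs with known logistic truth

small_spec <- function(n = 500, seed = 42, coef_mi = c(x1 = 1, x2 = -0.5),
                       intercept = -1, missing_rate = 0) {
  cohort_spec(
    n = n, seed = seed,
    numeric_features = data.frame(name = c("x1", "x2"), mean = c(0, 0),
                                  sd = c(1, 1), stringsAsFactors = FALSE),
    categorical_features = list(
      grp = list(levels = c("a", "b"), probs = c(0.5, 0.5))),
    outcome_models = list(y = list(intercept = intercept, coef = coef_mi)),
    protected = "grp", missing_rate = missing_rate)
}

# brute-force AUC: enumerate every positive-negative pair, ties counted 1/2
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# printed overall and subgroup AUC inputs for every model/outcome/attribute
# cell of the worked examples, with the printed RPPS
published_rpps_battery <- function() {
  rows <- rbind(
    # outcome, model, attribute, overall, sub1, sub2, printed rpps
    c("mi", "naive_bayes", "gender", 0.694, 0.667, 0.708, 0.961),
    c("mi", "svm", "gender", 0.581, 0.558, 0.675, 0.838),
    c("mi", "random_forest", "gender", 0.716, 0.673, 0.760, 0.939),
    c("mi", "xgboost", "gender", 0.695, 0.655, 0.753, 0.917),
    c("mi", "glmnet", "gender", 0.704, 0.689, 0.702, 0.979),
    c("mi", "oct", "gender", 0.687, 0.642, 0.763, 0.889),
    c("mi", "ofs", "gender", 0.705, 0.688, 0.716, 0.976),
    c("mi", "naive_bayes", "race", 0.694, 0.745, 0.681, 0.927),
    c("mi", "svm", "race", 0.581, 0.605, 0.591, 0.959),
    c("mi", "random_forest", "race", 0.716, 0.770, 0.704, 0.925),
    c("mi", "xgboost", "race", 0.695, 0.720, 0.690, 0.964),
    c("mi", "glmnet", "race", 0.704, 0.681, 0.706, 0.967),
    c("mi", "oct", "race", 0.687, 0.710, 0.682, 0.967),
    c("mi", "ofs", "race", 0.705, 0.668, 0.708, 0.948),
    c("stroke", "naive_bayes", "gender", 0.703, 0.679, 0.662, 0.942),
    c("stroke", "svm", "gender", 0.624, 0.622, 0.615, 0.986),
    c("stroke", "random_forest", "gender", 0.716, 0.783, 0.673, 0.906),
    c("stroke", "xgboost", "gender", 0.714, 0.773, 0.645, 0.903),
    c("stroke", "glmnet", "gender", 0.700, 0.714, 0.727, 0.961),
    c("stroke", "oct", "gender", 0.625, 0.595, 0.670, 0.928),
    c("stroke", "ofs", "gender", 0.731, 0.687, 0.787, 0.923),
    c("stroke", "naive_bayes", "race", 0.703, 0.733, 0.629, 0.895),
    c("stroke", "svm", "race", 0.624, 0.600, 0.609, 0.962),
    c("stroke", "random_forest", "race", 0.716, 0.741, 0.696, 0.965),
    c("stroke", "xgboost", "race", 0.714, 0.718, 0.702, 0.983),
    c("stroke", "glmnet", "race", 0.700, 0.685, 0.698, 0.979),
    c("stroke", "oct", "race", 0.625, 0.701, 0.582, 0.878),
    c("stroke", "ofs", "race", 0.731, 0.692, 0.743, 0.947))
  data.frame(outcome = rows[, 1], model = rows[, 2], attribute = rows[, 3],
             overall = as.numeric(rows[, 4]), sub1 = as.numeric(rows[, 5]),
             sub2 = as.numeric(rows[, 6]), rpps = as.numeric(rows[, 7]),
             stringsAsFactors = FALSE)
}
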