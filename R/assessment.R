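#' Area under the ROC curve (rank statistic)
#'
#' Probability that a randomly chosen positive case outscores a randomly
#' chosen negative case, with ties counted one half. Computed from the
#' Wilcoxon rank sum; identical to the trapezoidal area under the empirical
#' ROC curve and invariant under strictly increasing transforms of the
#' scores.
#'
#' @param scores Numeric score vector (higher = more likely positive).
#' @param labels Binary 0/1 vector; both classes must be present.
#' @return AUC in [0,1].
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary(labels)
  stopifnot(length(scores) == length(y))
  n1 <- as.numeric(sum(y == 1)); n0 <- as.numeric(sum(y == 0))
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix metrics at a threshold
#'
#' Applies the rule "predict positive when score >= threshold" and returns
#' sensitivity (true positive rate), specificity (true negative rate) and
#' overall accuracy.
#'
#' @inheritParams roc_auc
#' @param threshold Classification threshold.
#' @return Named numeric vector `c(sensitivity, specificity, accuracy)`.
#' @export
confusion_metrics <- function(scores, labels, threshold) {
  y <- as_binary(labels)
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0); fp <- sum(pred == 1 & y == 0)
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    accuracy = (tp + tn) / length(y))
}

#' Threshold optimizing a weighted sensitivity/specificity criterion
#'
#' Scans all observed unique scores as candidate thresholds and returns the
#' one maximizing `u * sensitivity + (1 - u) * specificity`. The default
#' `u = 2/3` leans toward sensitivity, reflecting the clinical cost of
#' missing a true event; ties are broken toward the lower threshold (higher
#' sensitivity).
#'
#' @inheritParams roc_auc
#' @param u Sensitivity weight in [0,1]; default `2/3`.
#' @return A `performance_report`: list with `auc`, `sensitivity`,
#'   `specificity`, `accuracy`, `threshold`, `u`.
#' @export
optimize_threshold <- function(scores, labels, u = 2 / 3) {
  if (!(u >= 0 && u <= 1)) stop("u must lie in [0,1]", call. = FALSE)
  y <- as_binary(labels)
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  cand <- sort(unique(scores))
  obj <- vapply(cand, function(t) {
    m <- confusion_metrics(scores, y, t)
    u * m[["sensitivity"]] + (1 - u) * m[["specificity"]]
  }, numeric(1))
  # ties toward lower threshold = higher sensitivity
  t_best <- cand[which(obj >= max(obj) - 1e-12)[1]]
  m <- confusion_metrics(scores, y, t_best)
  structure(list(auc = roc_auc(scores, y),
                 sensitivity = m[["sensitivity"]],
                 specificity = m[["specificity"]],
                 accuracy = m[["accuracy"]],
                 threshold = t_best, u = u),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("Performance at threshold %.4f (u = %.3f):\n", x$threshold, x$u))
  cat(sprintf("  AUC %.3f | sensitivity %.3f | specificity %.3f | accuracy %.3f\n",
              x$auc, x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' Subgroup-conditional AUCs
#'
#' ROC AUC restricted to the rows of each subgroup of a protected attribute.
#' Subgroups whose rows contain a single outcome class are unevaluable:
#' they are reported as `NA` with a warning (and later excluded from RPPS).
#' Empty subgroups are absent from the result.
#'
#' @inheritParams roc_auc
#' @param groups Vector of subgroup labels, one per row.
#' @return Named numeric vector of per-subgroup AUCs.
#' @export
subgroup_auc <- function(scores, labels, groups) {
  y <- as_binary(labels)
  stopifnot(length(groups) == length(y), length(scores) == length(y))
  g <- as.character(groups)
  out <- c()
  for (s in unique(g)) {
    idx <- which(g == s)
    if (length(idx) == 0) next
    if (length(unique(y[idx])) < 2) {
      warning(sprintf("subgroup '%s' has a single outcome class; AUC unevaluable", s),
              call. = FALSE)
      out[s] <- NA_real_
    } else {
      out[s] <- roc_auc(scores[idx], y[idx])
    }
  }
  out
}

#' Relative Parity of Performance Score (RPPS)
#'
#' `RPPS = 1 - max_s |AUC_s - AUC| / AUC`, the complement of the largest
#' relative deviation of any subgroup's conditional AUC from the overall
#' AUC. RPPS equals 1 under perfect parity and is deliberately not clamped:
#' it can go negative when a subgroup deviates by more than the overall AUC
#' itself. Unevaluable subgroups (`NA`) are excluded from the max with a
#' warning. The base metric is AUC by default, but any performance metric
#' can be supplied through the same two arguments.
#'
#' @param overall_auc Overall (population) AUC; must be positive.
#' @param subgroup_aucs Named numeric vector of subgroup-conditional AUCs.
#' @return RPPS, a real number <= 1.
#' @export
rpps <- function(overall_auc, subgroup_aucs) {
  if (!is.numeric(overall_auc) || length(overall_auc) != 1 || overall_auc <= 0) {
    stop("overall_auc must be a positive scalar", call. = FALSE)
  }
  if (any(is.na(subgroup_aucs))) {
    warning("excluding unevaluable subgroup(s) from RPPS", call. = FALSE)
    subgroup_aucs <- subgroup_aucs[!is.na(subgroup_aucs)]
  }
  if (length(subgroup_aucs) == 0) stop("no evaluable subgroups", call. = FALSE)
  1 - max(abs(subgroup_aucs - overall_auc)) / overall_auc
}

#' Assess one fitted model: performance and fairness
#'
#' Stage 1 of the workflow. Scores the test rows, optimizes the
#' classification threshold under the weighted sensitivity/specificity
#' criterion, and computes a fairness report (subgroup-conditional AUCs and
#' RPPS) per protected attribute. RPPS is threshold-free: it is built from
#' AUCs only.
#'
#' @param model A fitted [risk_model()].
#' @param x Test design matrix.
#' @param y Test outcome labels (binary 0/1).
#' @param protected Named list (or data frame) of protected-attribute
#'   vectors aligned with the rows of `x`.
#' @param u Sensitivity weight for threshold optimization (default 2/3).
#' @return A `model_assessment`: list with `$performance`
#'   (a `performance_report`) and `$fairness` (named list of
#'   `fairness_report` objects, one per protected attribute).
#' @export
assess_model <- function(model, x, y, protected = list(), u = 2 / 3) {
  scores <- predict(model, x, type = "risk")
  perf <- optimize_threshold(scores, y, u = u)
  fair <- list()
  for (a in names(protected)) {
    sub <- subgroup_auc(scores, y, protected[[a]])
    fair[[a]] <- structure(list(attribute = a, overall_auc = perf$auc,
                                subgroup_aucs = sub,
                                rpps = rpps(perf$auc, sub)),
                           class = "fairness_report")
  }
  structure(list(performance = perf, fairness = fair, family = model$family),
            class = "model_assessment")
}

#' @export
print.fairness_report <- function(x, ...) {
  cat(sprintf("Fairness over '%s': overall AUC %.3f, RPPS %.3f\n",
              x$attribute, x$overall_auc, x$rpps))
  for (s in names(x$subgroup_aucs)) {
    cat(sprintf("  AUC | %s: %s\n", s,
                ifelse(is.na(x$subgroup_aucs[[s]]), "unevaluable",
                       sprintf("%.3f", x$subgroup_aucs[[s]]))))
  }
  invisible(x)
}

#' @export
print.model_assessment <- function(x, ...) {
  cat(sprintf("Assessment of %s model\n", x$family))
  print(x$performance)
  for (f in x$fairness) print(f)
  invisible(x)
}

#' Tabulate assessments across models
#'
#' Flattens a named list of [assess_model()] results into one row per model:
#' AUC, sensitivity, specificity, accuracy, and per (attribute, subgroup)
#' conditional AUC plus per-attribute RPPS.
#'
#' @param assessments Named list of `model_assessment` objects.
#' @return A data frame, one row per model.
#' @export
assessment_table <- function(assessments) {
  rows <- lapply(names(assessments), function(nm) {
    a <- assessments[[nm]]
    row <- data.frame(model = nm, auc = a$performance$auc,
                      sensitivity = a$performance$sensitivity,
                      specificity = a$performance$specificity,
                      accuracy = a$performance$accuracy,
                      threshold = a$performance$threshold,
                      stringsAsFactors = FALSE)
    for (f in a$fairness) {
      for (s in names(f$subgroup_aucs)) {
        row[[paste0("auc_", f$attribute, "_", s)]] <- f$subgroup_aucs[[s]]
      }
      row[[paste0("rpps_", f$attribute)]] <- f$rpps
    }
    row
  })
  do.call(rbind, rows)
}
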