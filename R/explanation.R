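#' Configuration for the model-explanation stage
#'
#' @param n_bootstrap Number of bootstrap refits for permutation importance
#'   (default 100).
#' @param permutations_per_feature Independent permutations averaged per
#'   feature within each replicate (default 1).
#' @param ci_level Percentile confidence level for importance intervals
#'   (default 0.95).
#' @param shapley_samples Number of feature orderings for the sampling
#'   Shapley estimator (default 64; exact enumeration is used instead when
#'   the number of features allows it).
#' @param pdp_grid_size Grid points for numeric partial-dependence curves
#'   (default 50).
#' @param top_k How many top-importance features get PDP curves in
#'   [explain_model()] (default 3).
#' @param background_samples Rows subsampled from the training set as the
#'   interventional Shapley background (default 100).
#' @param seed Integer seed.
#' @return An `explain_config` list.
#' @export
explain_config <- function(n_bootstrap = 100L, permutations_per_feature = 1L,
                           ci_level = 0.95, shapley_samples = 64L,
                           pdp_grid_size = 50L, top_k = 3L,
                           background_samples = 100L, seed = 1L) {
  stopifnot(n_bootstrap >= 1, permutations_per_feature >= 1,
            ci_level > 0, ci_level < 1, shapley_samples >= 1,
            pdp_grid_size >= 1, top_k >= 1, background_samples >= 1)
  structure(list(n_bootstrap = as.integer(n_bootstrap),
                 permutations_per_feature = as.integer(permutations_per_feature),
                 ci_level = ci_level,
                 shapley_samples = as.integer(shapley_samples),
                 pdp_grid_size = as.integer(pdp_grid_size),
                 top_k = as.integer(top_k),
                 background_samples = as.integer(background_samples),
                 seed = as.integer(seed)),
            class = "explain_config")
}

#' Bootstrapped permutation variable importance with percentile CIs
#'
#' For each of `n_bootstrap` replicates: resample training rows with
#' replacement, refit the model, compute a baseline AUC on the out-of-bag
#' rows, then for each feature permute its out-of-bag column and record the
#' AUC drop (baseline minus permuted). Reports per-feature mean importance
#' and a percentile confidence interval across replicates; negative values
#' are preserved, not floored. Out-of-bag evaluation avoids the optimism of
#' scoring the rows the replicate was trained on.
#'
#' @param fit_fun Fitting procedure `function(x, y, seed)` returning an
#'   object usable by [risk_scores()] (e.g. the closure refitting a chosen
#'   [risk_model()] configuration).
#' @param x Training design matrix.
#' @param y Training labels (binary 0/1).
#' @param config An [explain_config()].
#' @return An `importance_table` data frame: `feature`, `mean`, `lower`,
#'   `upper`, `rank` (1 = largest mean importance).
#' @export
bootstrap_permutation_importance <- function(fit_fun, x, y, config = explain_config()) {
  x <- as.matrix(x); y <- as_binary(y)
  n <- nrow(x); p <- ncol(x)
  drops <- matrix(NA_real_, config$n_bootstrap, p,
                  dimnames = list(NULL, colnames(x)))
  skipped <- 0L
  with_local_seed(config$seed, {
    for (b in seq_len(config$n_bootstrap)) {
      idx <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), unique(idx))
      if (length(oob) < 2 || length(unique(y[oob])) < 2 ||
          length(unique(y[idx])) < 2) {
        warning(sprintf("replicate %d skipped: out-of-bag rows single-class", b),
                call. = FALSE)
        skipped <- skipped + 1L
        next
      }
      fit <- fit_fun(x[idx, , drop = FALSE], y[idx],
                     seed = config$seed + b)
      x_oob <- x[oob, , drop = FALSE]
      base_auc <- roc_auc(risk_scores(fit, x_oob), y[oob])
      for (j in seq_len(p)) {
        perm_auc <- mean(vapply(seq_len(config$permutations_per_feature),
                                function(r) {
          xp <- x_oob
          xp[, j] <- xp[sample.int(nrow(xp)), j]
          roc_auc(risk_scores(fit, xp), y[oob])
        }, numeric(1)))
        drops[b, j] <- base_auc - perm_auc
      }
    }
  })
  if (skipped > config$n_bootstrap / 2) {
    stop("more than half of the bootstrap replicates were unevaluable", call. = FALSE)
  }
  alpha <- (1 - config$ci_level) / 2
  mean_imp <- colMeans(drops, na.rm = TRUE)
  ci <- apply(drops, 2, stats::quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE)
  out <- data.frame(feature = colnames(x), mean = unname(mean_imp),
                    lower = unname(ci[1, ]), upper = unname(ci[2, ]),
                    stringsAsFactors = FALSE)
  out$rank <- rank(-out$mean, ties.method = "first")
  structure(out, class = c("importance_table", "data.frame"),
            n_bootstrap = config$n_bootstrap, ci_level = config$ci_level,
            skipped = skipped)
}

#' @export
print.importance_table <- function(x, ...) {
  cat(sprintf("Permutation importance (AUC drop), %d bootstrap refits, %.0f%% percentile CIs\n",
              attr(x, "n_bootstrap"), 100 * attr(x, "ci_level")))
  print.data.frame(x[order(x$rank), ], row.names = FALSE, digits = 4)
  invisible(x)
}

#' @param x An `importance_table`.
#' @param ... Passed to `barplot`.
#' @rdname bootstrap_permutation_importance
#' @export
plot.importance_table <- function(x, ...) {
  o <- order(x$mean)
  mid <- graphics::barplot(x$mean[o], names.arg = x$feature[o], horiz = TRUE,
                           las = 1, xlab = "mean AUC drop",
                           xlim = range(c(0, x$lower, x$upper, x$mean)), ...)
  graphics::segments(x$lower[o], mid, x$upper[o], mid, lwd = 2)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Exact interventional Shapley values for a linear margin model
#'
#' For a model whose margin (log-odds) is `intercept + x %*% beta` and a
#' feature-independent (interventional) background distribution, the
#' Shapley value of feature i at row x is exactly
#' `beta_i * (x_i - mean(background_i))`, and the base value is the mean
#' background margin. Efficiency (base + sum of values = margin) holds to
#' machine precision.
#'
#' @param coefficients Named numeric coefficient vector on the encoded
#'   feature space.
#' @param intercept Model intercept.
#' @param x Design matrix of rows to explain.
#' @param background Design matrix of background rows (same columns).
#' @return A `shap_matrix`: list with `$values` (rows x features), `$base`
#'   (scalar base value), `$margin` (per-row model output), `$scale`
#'   (`"margin"`), and `$se` (0 here; the method is exact).
#' @export
shapley_linear_exact <- function(coefficients, intercept, x, background) {
  x <- as.matrix(x); background <- as.matrix(background)
  if (nrow(background) == 0) stop("background is empty", call. = FALSE)
  stopifnot(identical(colnames(x), colnames(background)))
  beta <- coefficients[colnames(x)]
  if (anyNA(beta)) stop("coefficients missing for some design columns", call. = FALSE)
  mu <- colMeans(background)
  phi <- sweep(x, 2, mu) * rep(beta, each = nrow(x))
  base <- intercept + sum(beta * mu)
  structure(list(values = phi, base = base,
                 margin = base + rowSums(phi), scale = "margin",
                 se = matrix(0, nrow(x), ncol(x), dimnames = dimnames(x)),
                 method = "linear_exact"),
            class = "shap_matrix")
}

#' Sampling estimator of interventional Shapley values
#'
#' Monte-Carlo permutation (Strumbelj-Kononenko) estimator on the margin
#' (log-odds) scale. For each sampled feature ordering, features are added
#' one at a time: "present" features take the explained row's values,
#' "absent" features are averaged over every background row, and the
#' marginal change in expected margin is credited to the feature just
#' added. When `factorial(p) <= shapley_samples` all orderings are
#' enumerated once, making the estimator exact under the interventional
#' expectation. Per-cell standard errors are reported across orderings.
#'
#' @param model A fitted [risk_model()] (or any object usable by
#'   [margin_scores()]).
#' @param x Design matrix of rows to explain.
#' @param background Background design matrix (same columns).
#' @param config An [explain_config()]; uses `shapley_samples` and `seed`.
#' @return A `shap_matrix` (see [shapley_linear_exact()]); `$se` holds the
#'   Monte-Carlo standard error of each value.
#' @export
shapley_sampling <- function(model, x, background, config = explain_config()) {
  x <- as.matrix(x); background <- as.matrix(background)
  if (nrow(background) == 0) stop("background is empty", call. = FALSE)
  stopifnot(identical(colnames(x), colnames(background)))
  p <- ncol(x); nx <- nrow(x); nb <- nrow(background)

  perms <- if (p <= 8 && factorial(p) <= config$shapley_samples) {
    all_permutations(p)
  } else {
    with_local_seed(config$seed,
      lapply(seq_len(config$shapley_samples), function(i) sample.int(p)))
  }
  nperm <- length(perms)

  # E[f | features S fixed to x-row values] estimated over all background rows
  expected_margin <- function(fixed_cols, xrow) {
    m <- background
    if (length(fixed_cols) > 0) {
      m[, fixed_cols] <- matrix(xrow[fixed_cols], nb, length(fixed_cols), byrow = TRUE)
    }
    mean(margin_scores(model, m))
  }

  contrib <- array(NA_real_, c(nx, p, nperm))
  for (q in seq_len(nperm)) {
    ord <- perms[[q]]
    for (i in seq_len(nx)) {
      prev <- expected_margin(integer(0), x[i, ])
      for (k in seq_len(p)) {
        cur <- expected_margin(ord[seq_len(k)], x[i, ])
        contrib[i, ord[k], q] <- cur - prev
        prev <- cur
      }
    }
  }
  phi <- apply(contrib, c(1, 2), mean)
  se <- apply(contrib, c(1, 2), stats::sd) / sqrt(nperm)
  dimnames(phi) <- dimnames(se) <- list(rownames(x), colnames(x))
  base <- mean(margin_scores(model, background))
  structure(list(values = phi, base = base,
                 margin = margin_scores(model, x), scale = "margin",
                 se = se, method = "sampling", n_orderings = nperm),
            class = "shap_matrix")
}

all_permutations <- function(p) {
  if (p == 1) return(list(1L))
  sub <- all_permutations(p - 1L)
  out <- list()
  for (s in sub) {
    for (pos in 0:(p - 1L)) {
      out[[length(out) + 1L]] <- append(s, p, after = pos)
    }
  }
  out
}

#' @export
print.shap_matrix <- function(x, ...) {
  cat(sprintf("Shapley values (%s method) on the %s scale: %d rows x %d features\n",
              x$method, x$scale, nrow(x$values), ncol(x$values)))
  cat(sprintf("  base value %.4f; per-feature mean |value|:\n", x$base))
  print(round(sort(colMeans(abs(x$values)), decreasing = TRUE), 4))
  invisible(x)
}

#' Relative Shapley values
#'
#' Divides each row's Shapley values by the row's total attribution
#' `sum(phi)` (= margin minus base value), so relative contributions sum to
#' 1 per row and are comparable across individuals. Rows whose total
#' attribution is (numerically) zero are flagged and excluded from the
#' per-feature means.
#'
#' @param shap A `shap_matrix` from [shapley_linear_exact()] or
#'   [shapley_sampling()].
#' @param tol Rows with `|sum(phi)| < tol` are treated as degenerate.
#' @return A `relative_shap_matrix`: `$values` (rows x features, `NA` for
#'   degenerate rows), `$degenerate` (logical per row), `$feature_means`.
#' @export
relative_shapley <- function(shap, tol = 1e-9) {
  stopifnot(inherits(shap, "shap_matrix"))
  tot <- rowSums(shap$values)
  degen <- abs(tot) < tol
  if (all(degen)) stop("all rows have zero total attribution", call. = FALSE)
  rel <- shap$values / tot
  rel[degen, ] <- NA_real_
  structure(list(values = rel, degenerate = degen,
                 feature_means = colMeans(rel[!degen, , drop = FALSE])),
            class = "relative_shap_matrix")
}

#' @export
print.relative_shap_matrix <- function(x, ...) {
  cat(sprintf("Relative Shapley values: %d rows (%d degenerate excluded)\n",
              nrow(x$values), sum(x$degenerate)))
  cat("Per-feature mean relative contribution:\n")
  print(round(sort(x$feature_means, decreasing = TRUE), 4))
  invisible(x)
}

#' Partial dependence of model output on one feature
#'
#' Sweeps one design column over a grid (equally spaced across its observed
#' range for numeric features; its observed values for binary indicators),
#' sets the column to each grid value in every row, and averages the model
#' output over rows. Both scales are returned: mean risk and mean log-odds
#' (the average of per-row margins). A histogram of the feature's observed
#' values indicates where the curve is supported by data.
#'
#' @param model A fitted [risk_model()].
#' @param x Design matrix (typically the training or test rows).
#' @param feature Column name to sweep.
#' @param config An [explain_config()]; uses `pdp_grid_size`.
#' @return A `pdp_curve`: data frame `$curve` with `value`, `mean_risk`,
#'   `mean_logodds`; plus `$feature` and `$density` (histogram of observed
#'   values).
#' @export
partial_dependence <- function(model, x, feature, config = explain_config()) {
  x <- as.matrix(x)
  if (!feature %in% colnames(x)) {
    stop(sprintf("unknown feature '%s'", feature), call. = FALSE)
  }
  obs <- x[, feature]
  vals <- sort(unique(obs))
  grid <- if (length(vals) <= 2 || all(vals %in% c(0, 1))) {
    vals
  } else {
    seq(min(obs), max(obs), length.out = config$pdp_grid_size)
  }
  res <- t(vapply(grid, function(v) {
    xv <- x
    xv[, feature] <- v
    c(mean_risk = mean(risk_scores(model, xv)),
      mean_logodds = mean(margin_scores(model, xv)))
  }, c(mean_risk = 0, mean_logodds = 0)))
  dens <- graphics::hist(obs, plot = FALSE)
  structure(list(feature = feature,
                 curve = data.frame(value = grid, mean_risk = res[, "mean_risk"],
                                    mean_logodds = res[, "mean_logodds"]),
                 density = list(breaks = dens$breaks, counts = dens$counts)),
            class = "pdp_curve")
}

#' @export
print.pdp_curve <- function(x, ...) {
  cat(sprintf("Partial dependence of model output on '%s' (%d grid points)\n",
              x$feature, nrow(x$curve)))
  cat(sprintf("  mean log-odds %.3f to %.3f; mean risk %.3f to %.3f over the grid\n",
              x$curve$mean_logodds[1], x$curve$mean_logodds[nrow(x$curve)],
              x$curve$mean_risk[1], x$curve$mean_risk[nrow(x$curve)]))
  invisible(x)
}

#' @param x A `pdp_curve`.
#' @param scale Which output scale to draw.
#' @param ... Passed to `plot`.
#' @rdname partial_dependence
#' @export
plot.pdp_curve <- function(x, scale = c("logodds", "risk"), ...) {
  scale <- match.arg(scale)
  yv <- if (scale == "logodds") x$curve$mean_logodds else x$curve$mean_risk
  graphics::plot(x$curve$value, yv, type = "l", lwd = 2, xlab = x$feature,
                 ylab = if (scale == "logodds") "mean log-odds" else "mean risk",
                 ...)
  mids <- (x$density$breaks[-1] + x$density$breaks[-length(x$density$breaks)]) / 2
  inside <- mids >= min(x$curve$value) & mids <= max(x$curve$value)
  graphics::rug(rep(mids[inside], x$density$counts[inside] %/%
                      max(1, max(x$density$counts) %/% 50)))
  invisible(x)
}

#' Integrated model explanation (stage 3)
#'
#' Composes the three explanation methods on a fitted model: bootstrapped
#' permutation importance with confidence intervals, Shapley values on the
#' log-odds scale (exact for penalized-logistic models, sampling estimator
#' otherwise) with their relative form, and partial-dependence curves for
#' the `top_k` features ranked by mean permutation importance.
#'
#' @param model A fitted [risk_model()].
#' @param x Training design matrix.
#' @param y Training labels.
#' @param config An [explain_config()].
#' @return A `model_explanation`: `$importance` (importance_table),
#'   `$shapley` (shap_matrix), `$relative_shapley`, `$pdp` (named list of
#'   pdp_curve for the top-k features), `$top_features`.
#' @export
explain_model <- function(model, x, y, config = explain_config()) {
  x <- as.matrix(x)
  imp <- bootstrap_permutation_importance(refit_fun(model), x, y, config)
  background <- if (nrow(x) > config$background_samples) {
    x[with_local_seed(config$seed,
                      sample.int(nrow(x), config$background_samples)), ,
      drop = FALSE]
  } else x
  shap <- if (model$family == "glmnet") {
    b <- coef(model)
    shapley_linear_exact(b[-1], b[["(Intercept)"]], x, background)
  } else {
    shapley_sampling(model, x, background, config)
  }
  rel <- relative_shapley(shap)
  k <- min(config$top_k, ncol(x))
  top <- imp$feature[order(imp$rank)][seq_len(k)]
  pdp <- lapply(top, function(f) partial_dependence(model, x, f, config))
  names(pdp) <- top
  structure(list(importance = imp, shapley = shap, relative_shapley = rel,
                 pdp = pdp, top_features = top),
            class = "model_explanation")
}

#' @export
print.model_explanation <- function(x, ...) {
  print(x$importance)
  cat("\n")
  print(x$relative_shapley)
  cat("\nPartial dependence computed for:",
      paste(x$top_features, collapse = ", "), "\n")
  invisible(x)
}
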