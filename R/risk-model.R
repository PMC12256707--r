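#' Fit a binary risk classifier behind a uniform adapter contract
#'
#' One fitting surface over several classifier families so that assessment,
#' selection and explanation stay model-agnostic. Hyperparameters are tuned
#' by 10-fold cross-validated AUC over a grid, then the winning configuration
#' is refit on all rows. Every fitted model exposes the same contract:
#' `predict(type = "risk")` returns event probabilities in [0,1] and
#' `predict(type = "margin")` their log-odds (risk clamped to
#' [1e-12, 1-1e-12] before the logit).
#'
#' Families: `"glmnet"` (elastic-net penalized logistic regression),
#' `"cart"` (greedy decision tree, depth-limited), `"random_forest"`,
#' `"xgboost"` (gradient boosting), `"naive_bayes"`, and `"svm"` (RBF kernel
#' with Platt-calibrated probabilities). Class weights are applied where the
#' backend supports them (per-row loss weights for glmnet/cart/xgboost,
#' class priors/weights for random forest and SVM; naive Bayes fits class
#' priors from the data).
#'
#' @param x Numeric design matrix (see [encode_one_hot()]).
#' @param y Binary 0/1 outcome vector.
#' @param family Classifier family; see Details.
#' @param grid Hyperparameter grid: a data frame of combinations or a named
#'   list of candidate vectors (expanded by `expand.grid`). `NULL` uses a
#'   small per-family default.
#' @param weights Optional named class-weight vector `c("0"=, "1"=)` as from
#'   [class_weights()].
#' @param nfolds Number of cross-validation folds (default 10).
#' @param seed Integer seed controlling fold assignment and any stochastic
#'   fitting.
#' @return An object of class `risk_model` with elements `family`,
#'   `hyperparameters` (the chosen grid row), `cv_results` (mean CV AUC per
#'   grid row), `fit`, and `feature_names`.
#' @examples
#' spec <- accord_like_spec(n = 400, calibrate = FALSE, missing_rate = 0)
#' tab <- generate_cohort(spec)
#' x <- encode_one_hot(tab)
#' m <- risk_model(x, tab$mi, family = "glmnet",
#'                 grid = list(alpha = 0.5, lambda = 0.01), seed = 1)
#' head(predict(m, x))
#' @export
risk_model <- function(x, y,
                       family = c("glmnet", "cart", "random_forest", "xgboost",
                                  "naive_bayes", "svm"),
                       grid = NULL, weights = NULL, nfolds = 10L, seed = 1L) {
  family <- match.arg(family)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as_binary(y, "y")
  if (length(y) != nrow(x)) stop("x and y disagree on row count", call. = FALSE)
  if (length(unique(y)) < 2) stop("both classes must be present in y", call. = FALSE)

  grid <- normalize_grid(grid %||% default_grid(family, ncol(x)))
  cv_auc <- rep(NA_real_, nrow(grid))
  if (nrow(grid) > 1) {
    if (nrow(x) < nfolds) stop("fewer rows than cross-validation folds", call. = FALSE)
    folds <- with_local_seed(seed, sample(rep_len(seq_len(nfolds), nrow(x))))
    for (g in seq_len(nrow(grid))) {
      params <- as.list(grid[g, , drop = FALSE])
      fold_auc <- vapply(seq_len(nfolds), function(k) {
        tr <- folds != k
        if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) return(NA_real_)
        fit <- tryCatch(
          fit_backend(family, params, x[tr, , drop = FALSE], y[tr], weights, seed),
          error = function(e) NULL)
        if (is.null(fit)) return(NA_real_)
        roc_auc(predict_backend(family, fit, x[!tr, , drop = FALSE]), y[!tr])
      }, numeric(1))
      cv_auc[g] <- mean(fold_auc, na.rm = TRUE)
    }
    best <- which.max(cv_auc)
  } else {
    best <- 1L
  }
  chosen <- as.list(grid[best, , drop = FALSE])
  fit <- fit_backend(family, chosen, x, y, weights, seed)

  structure(list(family = family, hyperparameters = chosen,
                 cv_results = cbind(grid, cv_auc = cv_auc),
                 fit = fit, feature_names = colnames(x),
                 weights = weights, nfolds = nfolds, seed = seed,
                 n = nrow(x)),
            class = "risk_model")
}

normalize_grid <- function(grid) {
  if (is.data.frame(grid)) {
    if (nrow(grid) == 0) stop("hyperparameter grid is empty", call. = FALSE)
    return(grid)
  }
  if (is.list(grid)) {
    if (length(grid) == 0) stop("hyperparameter grid is empty", call. = FALSE)
    return(expand.grid(grid, stringsAsFactors = FALSE))
  }
  stop("grid must be a data frame or named list", call. = FALSE)
}

default_grid <- function(family, p) {
  switch(family,
    glmnet        = expand.grid(alpha = 0.5, lambda = c(0.001, 0.01, 0.1)),
    cart          = expand.grid(maxdepth = c(3, 4), cp = c(0.001, 0.01)),
    random_forest = expand.grid(ntree = 300,
                                mtry = unique(pmax(1, c(floor(sqrt(p)), floor(p / 2))))),
    xgboost       = expand.grid(max_depth = c(2, 3), eta = 0.1, nrounds = c(50, 150)),
    naive_bayes   = expand.grid(laplace = c(0, 1)),
    svm           = expand.grid(cost = c(0.1, 1)))
}

# per-row loss weights from a class-weight map
row_weights <- function(weights, y) {
  if (is.null(weights)) rep(1, length(y)) else unname(weights[as.character(y)])
}

# data-frame view with syntactically safe column names (some backends
# mangle names like "gender=women")
safe_df <- function(x) {
  dd <- as.data.frame(x)
  colnames(dd) <- make.names(colnames(x), unique = TRUE)
  dd
}

fit_backend <- function(family, params, x, y, weights, seed) {
  w <- row_weights(weights, y)
  switch(family,
    glmnet = {
      lam <- params$lambda %||% 0.01
      path <- sort(unique(c(lam, lam * 2, lam * 10, lam * 100)), decreasing = TRUE)
      fit <- glmnet::glmnet(x, y, family = "binomial", weights = w,
                            alpha = params$alpha %||% 0.5, lambda = path)
      list(fit = fit, lambda = lam)
    },
    cart = {
      dd <- safe_df(x); dd$.y <- factor(y, levels = c(0, 1))
      ctl <- rpart::rpart.control(maxdepth = params$maxdepth %||% 4,
                                  cp = params$cp %||% 0.01,
                                  minbucket = params$minbucket %||% 7, xval = 0)
      fit <- with_local_seed(seed,
        do.call(rpart::rpart,
                list(formula = .y ~ ., data = dd, weights = w,
                     method = "class", control = ctl)))
      list(fit = fit)
    },
    random_forest = {
      dd <- safe_df(x)
      cw <- if (is.null(weights)) NULL else unname(weights[c("0", "1")])
      fit <- with_local_seed(seed,
        randomForest::randomForest(x = dd, y = factor(y, levels = c(0, 1)),
                                   ntree = params$ntree %||% 300,
                                   mtry = params$mtry %||% max(1, floor(sqrt(ncol(x)))),
                                   classwt = cw))
      list(fit = fit)
    },
    xgboost = {
      dtrain <- xgboost::xgb.DMatrix(x, label = y, weight = w, nthread = 1)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = params$max_depth %||% 3,
                      eta = params$eta %||% 0.1, nthread = 1,
                      seed = seed),
        data = dtrain, nrounds = params$nrounds %||% 100, verbose = 0)
      list(fit = fit)
    },
    naive_bayes = {
      dd <- safe_df(x)
      fit <- e1071::naiveBayes(x = dd, y = factor(y, levels = c(0, 1)),
                               laplace = params$laplace %||% 0)
      list(fit = fit)
    },
    svm = {
      cw <- if (is.null(weights)) NULL else weights[c("0", "1")]
      fit <- with_local_seed(seed, suppressWarnings(
        e1071::svm(x = x, y = factor(y, levels = c(0, 1)),
                   cost = params$cost %||% 1, kernel = "radial",
                   probability = TRUE, class.weights = cw)))
      list(fit = fit)
    })
}

predict_backend <- function(family, fit, x) {
  p <- switch(family,
    glmnet = as.numeric(stats::predict(fit$fit, newx = x, s = fit$lambda,
                                       type = "response")),
    cart = stats::predict(fit$fit, newdata = safe_df(x), type = "prob")[, "1"],
    random_forest = stats::predict(fit$fit, newdata = safe_df(x),
                                   type = "prob")[, "1"],
    xgboost = as.numeric(stats::predict(fit$fit,
                                        xgboost::xgb.DMatrix(x, nthread = 1))),
    naive_bayes = stats::predict(fit$fit, newdata = safe_df(x),
                                 type = "raw")[, "1"],
    svm = {
      pr <- stats::predict(fit$fit, newdata = x, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    })
  unname(pmin(pmax(as.numeric(p), 0), 1))
}

#' @rdname risk_model
#' @param object,model A fitted `risk_model`.
#' @param newdata Design matrix with the training columns.
#' @param type `"risk"` for probabilities, `"margin"` for log-odds.
#' @param ... Unused.
#' @export
predict.risk_model <- function(object, newdata, type = c("risk", "margin"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata)) ||
      !identical(colnames(newdata), object$feature_names)) {
    stop("newdata columns do not match the training design matrix", call. = FALSE)
  }
  p <- predict_backend(object$family, object$fit, newdata)
  if (type == "risk") p else clamp_logit(p)
}

#' Risk and margin scores (adapter contract)
#'
#' `risk_scores()` returns per-row event probabilities in [0,1];
#' `margin_scores()` their log-odds with risk clamped to [1e-12, 1-1e-12]
#' so margins stay finite.
#'
#' @param model A fitted [risk_model()].
#' @param x Design matrix with the training columns.
#' @return Numeric vector, one value per row of `x`.
#' @export
risk_scores <- function(model, x) predict(model, x, type = "risk")

#' @rdname risk_scores
#' @export
margin_scores <- function(model, x) predict(model, x, type = "margin")

#' Coefficients of a penalized-logistic risk model
#'
#' Returns the fitted coefficients on the encoded feature space; features
#' zeroed out by the penalty are reported as 0. Only defined for the
#' `"glmnet"` family.
#'
#' @param object A fitted `risk_model` of family `"glmnet"`.
#' @param ... Unused.
#' @return Named numeric vector; first element `"(Intercept)"`.
#' @export
coef.risk_model <- function(object, ...) {
  if (object$family != "glmnet") {
    stop(sprintf("coefficients are unsupported for family '%s'", object$family),
         call. = FALSE)
  }
  b <- stats::coef(object$fit$fit, s = object$fit$lambda)
  stats::setNames(as.numeric(b), rownames(b))
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("Risk classifier (family: %s), fit on %d rows x %d features\n",
              x$family, x$n, length(x$feature_names)))
  hp <- paste(names(x$hyperparameters),
              vapply(x$hyperparameters, format, character(1)), sep = "=")
  cat("  hyperparameters:", paste(hp, collapse = ", "), "\n")
  if (!all(is.na(x$cv_results$cv_auc))) {
    cat(sprintf("  cross-validated AUC at chosen point: %.3f\n",
                max(x$cv_results$cv_auc, na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
summary.risk_model <- function(object, ...) {
  print(object)
  if (nrow(object$cv_results) > 1) {
    cat("CV grid:\n")
    print(object$cv_results, row.names = FALSE)
  }
  invisible(object)
}

# refitting closure used by bootstrap explanation: same family,
# chosen hyperparameters, re-derived class weights
refit_fun <- function(model) {
  force(model)
  function(x, y, seed = model$seed) {
    w <- if (is.null(model$weights)) NULL else class_weights(y)
    risk_model(x, y, family = model$family,
               grid = as.data.frame(model$hyperparameters),
               weights = w, seed = seed)
  }
}
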