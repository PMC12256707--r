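#' Declare column roles for a cohort table
#'
#' Partitions the columns of a cohort table into outcomes, protected
#' attributes and predictors. Protected attributes may also appear among the
#' predictors (demographics routinely enter clinical risk models); otherwise
#' the role sets must be disjoint. Categorical predictors carry an ordered
#' level list whose first element is the reference level for dummy coding.
#'
#' @param outcomes Character vector of binary outcome column names.
#' @param protected Character vector of protected-attribute column names.
#' @param predictors Character vector of predictor column names.
#' @param categorical_levels Named list: for each categorical predictor, its
#'   ordered character vector of levels (first = reference).
#' @return An object of class `column_roles`.
#' @export
column_roles <- function(outcomes, protected = character(), predictors,
                         categorical_levels = list()) {
  stopifnot(is.character(outcomes), is.character(protected), is.character(predictors))
  if (length(intersect(outcomes, predictors)) > 0) {
    stop("outcome columns cannot also be predictors: ",
         paste(intersect(outcomes, predictors), collapse = ", "), call. = FALSE)
  }
  if (length(intersect(outcomes, protected)) > 0) {
    stop("outcome columns cannot also be protected attributes", call. = FALSE)
  }
  bad <- setdiff(names(categorical_levels), predictors)
  if (length(bad) > 0) {
    stop("categorical_levels given for non-predictor columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  for (nm in names(categorical_levels)) {
    lv <- categorical_levels[[nm]]
    if (length(lv) < 2 || anyDuplicated(lv)) {
      stop(sprintf("categorical predictor '%s' needs >= 2 distinct levels", nm),
           call. = FALSE)
    }
  }
  structure(list(outcomes = outcomes, protected = protected,
                 predictors = predictors,
                 categorical_levels = categorical_levels),
            class = "column_roles")
}

#' @export
print.column_roles <- function(x, ...) {
  cat("Column roles\n")
  cat("  outcomes:  ", paste(x$outcomes, collapse = ", "), "\n")
  cat("  protected: ", paste(x$protected, collapse = ", "), "\n")
  cat("  predictors:", length(x$predictors), "total,",
      length(x$categorical_levels), "categorical\n")
  invisible(x)
}

roles_of <- function(table, roles = NULL) {
  roles <- roles %||% attr(table, "roles")
  if (is.null(roles)) stop("no column roles supplied or attached to the table", call. = FALSE)
  missing_cols <- setdiff(c(roles$outcomes, roles$protected, roles$predictors),
                          names(table))
  if (length(missing_cols) > 0) {
    stop("columns named in roles are absent from the table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  roles
}

#' Complete-case filter over role columns
#'
#' Drops every row carrying a missing value in any outcome, protected or
#' predictor column, mirroring complete-case model development without
#' imputation. Cells in columns outside the declared roles are ignored.
#'
#' @param table A cohort data frame.
#' @param roles A [column_roles()] object; taken from `attr(table, "roles")`
#'   when omitted.
#' @param quiet Suppress the message reporting how many rows were dropped.
#' @return The filtered table (roles attribute preserved).
#' @export
drop_incomplete <- function(table, roles = NULL, quiet = FALSE) {
  if (nrow(table) == 0) stop("table is empty", call. = FALSE)
  roles <- roles_of(table, roles)
  cols <- unique(c(roles$outcomes, roles$protected, roles$predictors))
  keep <- stats::complete.cases(table[, cols, drop = FALSE])
  if (!any(keep)) stop("all rows have missing values in role columns", call. = FALSE)
  if (!quiet && sum(!keep) > 0) {
    message(sprintf("drop_incomplete: removed %d of %d rows with missing values",
                    sum(!keep), nrow(table)))
  }
  out <- table[keep, , drop = FALSE]
  attr(out, "roles") <- roles
  out
}

#' Reference-coded one-hot design matrix
#'
#' Encodes the predictor columns into a numeric matrix. Each categorical
#' predictor with k levels becomes k-1 indicator columns named
#' `"<feature>=<level>"`, omitting the first (reference) level; numeric
#' predictors pass through unchanged. Rows must be complete cases.
#'
#' @param table A complete-case cohort data frame.
#' @param roles A [column_roles()] object (or attached to the table).
#' @return Numeric matrix with rownames carrying the row identifiers and a
#'   `"roles"` attribute.
#' @export
encode_one_hot <- function(table, roles = NULL) {
  roles <- roles_of(table, roles)
  cols <- list()
  for (p in roles$predictors) {
    if (p %in% names(roles$categorical_levels)) {
      lv <- roles$categorical_levels[[p]]
      obs <- as.character(table[[p]])
      unseen <- setdiff(unique(obs[!is.na(obs)]), lv)
      if (length(unseen) > 0) {
        stop(sprintf("unseen level(s) in '%s': %s", p,
                     paste(unseen, collapse = ", ")), call. = FALSE)
      }
      for (l in lv[-1]) {
        cols[[paste0(p, "=", l)]] <- as.numeric(obs == l)
      }
    } else {
      v <- table[[p]]
      if (!is.numeric(v)) {
        stop(sprintf("predictor '%s' is non-numeric but has no declared levels", p),
             call. = FALSE)
      }
      cols[[p]] <- as.numeric(v)
    }
  }
  x <- do.call(cbind, cols)
  if (anyNA(x)) stop("design matrix contains missing values; run drop_incomplete() first",
                     call. = FALSE)
  rownames(x) <- rownames(table)
  attr(x, "roles") <- roles
  x
}

#' Random train/test partition
#'
#' Uniformly random, unstratified split. The training size is
#' `fraction * n_rows` rounded half up, so a 70/30 split of 9635 rows gives
#' 6745 training and 2890 test rows. Set `stratify_by` to a binary outcome
#' vector to split within each class instead (off by default).
#'
#' @param n_rows Number of rows to partition.
#' @param fraction Training fraction in (0,1); default 0.7.
#' @param seed Integer seed making the partition reproducible.
#' @param stratify_by Optional vector of length `n_rows`; when given, the
#'   split is performed within each of its levels.
#' @return A `split_indices` object: list with sorted integer vectors
#'   `$train` and `$test` and the `$seed`.
#' @export
split_train_test <- function(n_rows, fraction = 0.7, seed = 1L, stratify_by = NULL) {
  stopifnot(n_rows >= 2, fraction > 0, fraction < 1)
  n_train <- floor(fraction * n_rows + 0.5)  # round half up
  if (n_train < 1 || n_train >= n_rows) {
    stop("degenerate split: one side would be empty", call. = FALSE)
  }
  train <- with_local_seed(seed, {
    if (is.null(stratify_by)) {
      sample.int(n_rows, n_train)
    } else {
      stopifnot(length(stratify_by) == n_rows)
      idx <- split(seq_len(n_rows), stratify_by)
      unlist(lapply(idx, function(i) {
        sample(i, floor(fraction * length(i) + 0.5))
      }), use.names = FALSE)
    }
  })
  train <- sort(train)
  structure(list(train = train, test = setdiff(seq_len(n_rows), train), seed = seed),
            class = "split_indices")
}

#' Balanced inverse-frequency class weights
#'
#' Computes `weight(c) = n_total / (2 * n_c)` for each class of a binary
#' label vector, the balanced weighting used to counter class imbalance when
#' fitting classifiers on rare-event outcomes.
#'
#' @param labels Binary 0/1 vector with both classes present.
#' @return Named numeric vector `c("0" = w0, "1" = w1)`.
#' @export
class_weights <- function(labels) {
  y <- as_binary(labels)
  n0 <- sum(y == 0); n1 <- sum(y == 1)
  if (n0 == 0 || n1 == 0) stop("both classes must be present", call. = FALSE)
  n <- n0 + n1
  c("0" = n / (2 * n0), "1" = n / (2 * n1))
}
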