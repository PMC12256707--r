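#' Weighted accuracy-fairness score
#'
#' The stage-2 selection objective `w * accuracy + (1 - w) * rpps`. At
#' `w = 1` it reduces to accuracy; at `w = 0` to RPPS.
#'
#' @param accuracy Overall accuracy (at the optimized threshold).
#' @param rpps Relative Parity of Performance Score.
#' @param w Trade-off weight(s) in [0,1]; vectorized.
#' @return Numeric score(s).
#' @export
weighted_score <- function(accuracy, rpps, w) {
  if (any(w < 0 | w > 1)) stop("w must lie in [0,1]", call. = FALSE)
  w * accuracy + (1 - w) * rpps
}

#' Accuracy-fairness trade-off curve and dominance regions
#'
#' Scores every candidate model at each weight of a grid over [0,1], finds
#' the best model per weight (ties reported, not broken), and solves the
#' crossover weights between consecutive dominance regions exactly as the
#' intersections of the two models' affine score lines.
#'
#' @param models Data frame with columns `name`, `accuracy`, `rpps` (one row
#'   per model), or a list of such triples.
#' @param w_grid Weight grid; sorted, unique, within [0,1], containing both
#'   endpoints. Default `seq(0, 1, by = 0.05)`.
#' @return A `tradeoff_curve` object: `$scores` (model x weight matrix),
#'   `$best` (list per weight of all argmax model names), `$regions`
#'   (data frame of dominance intervals with the winning model set), and
#'   `$crossovers` (exact boundary weights).
#' @examples
#' tc <- tradeoff_curve(data.frame(name = c("A", "B"),
#'                                 accuracy = c(0.714, 0.833),
#'                                 rpps = c(0.961, 0.906)))
#' tc$crossovers  # 0.055 / 0.174
#' @export
tradeoff_curve <- function(models, w_grid = seq(0, 1, by = 0.05)) {
  if (is.list(models) && !is.data.frame(models)) {
    models <- do.call(rbind, lapply(models, function(m)
      data.frame(name = m$name %||% m[[1]], accuracy = m$accuracy %||% m[[2]],
                 rpps = m$rpps %||% m[[3]], stringsAsFactors = FALSE)))
  }
  stopifnot(is.data.frame(models), all(c("name", "accuracy", "rpps") %in% names(models)))
  if (nrow(models) == 0) stop("empty model list", call. = FALSE)
  if (!all(is.finite(models$accuracy)) || !all(is.finite(models$rpps))) {
    stop("accuracy and rpps must be finite", call. = FALSE)
  }
  w_grid <- sort(unique(w_grid))
  if (any(w_grid < 0 | w_grid > 1) || w_grid[1] != 0 || w_grid[length(w_grid)] != 1) {
    stop("w_grid must lie in [0,1] and include both endpoints", call. = FALSE)
  }

  scores <- outer(seq_len(nrow(models)), w_grid,
                  function(i, w) weighted_score(models$accuracy[i], models$rpps[i], w))
  dimnames(scores) <- list(models$name, format(w_grid))
  tol <- 1e-12
  best <- lapply(seq_along(w_grid), function(j) {
    models$name[scores[, j] >= max(scores[, j]) - tol]
  })
  names(best) <- format(w_grid)

  # continuous dominance regions: evaluate the argmax between consecutive
  # candidate breakpoints (all pairwise line intersections in (0,1))
  argmax_at <- function(w) {
    s <- weighted_score(models$accuracy, models$rpps, w)
    sort(models$name[s >= max(s) - tol])
  }
  cross_w <- c()
  if (nrow(models) > 1) {
    for (i in seq_len(nrow(models) - 1)) {
      for (k in (i + 1):nrow(models)) {
        da <- models$accuracy[i] - models$accuracy[k]
        dr <- models$rpps[i] - models$rpps[k]
        if (abs(da - dr) > tol) {
          w0 <- -dr / (da - dr)  # solves w*da + (1-w)*dr = 0
          if (w0 > tol && w0 < 1 - tol) cross_w <- c(cross_w, w0)
        }
      }
    }
  }
  bp <- sort(unique(c(0, cross_w, 1)))
  regions <- data.frame(w_lo = bp[-length(bp)], w_hi = bp[-1])
  regions$best <- vapply(seq_len(nrow(regions)), function(r) {
    paste(argmax_at((regions$w_lo[r] + regions$w_hi[r]) / 2), collapse = "+")
  }, character(1))
  # merge consecutive intervals with the same winner set
  keep <- c(TRUE, regions$best[-1] != regions$best[-nrow(regions)])
  merged <- regions[keep, , drop = FALSE]
  if (nrow(merged) > 1) {
    idx <- cumsum(keep)
    merged$w_hi <- as.numeric(tapply(regions$w_hi, factor(idx, levels = unique(idx)), max))
  }
  crossovers <- merged$w_lo[-1]

  structure(list(models = models, w_grid = w_grid, scores = scores,
                 best = best, regions = merged, crossovers = crossovers),
            class = "tradeoff_curve")
}

#' @export
print.tradeoff_curve <- function(x, ...) {
  cat(sprintf("Accuracy-fairness trade-off over %d models, %d grid weights\n",
              nrow(x$models), length(x$w_grid)))
  cat("Dominance regions (w * accuracy + (1 - w) * RPPS):\n")
  for (r in seq_len(nrow(x$regions))) {
    cat(sprintf("  w in [%.3f, %.3f]: %s\n", x$regions$w_lo[r],
                x$regions$w_hi[r], x$regions$best[r]))
  }
  invisible(x)
}

#' @param x A `tradeoff_curve` object.
#' @param ... Passed to `matplot`.
#' @rdname tradeoff_curve
#' @export
plot.tradeoff_curve <- function(x, ...) {
  dense_w <- seq(0, 1, length.out = 201)
  sc <- sapply(seq_len(nrow(x$models)), function(i)
    weighted_score(x$models$accuracy[i], x$models$rpps[i], dense_w))
  graphics::matplot(dense_w, sc, type = "l", lty = 1, lwd = 2,
                    xlab = "weight w on accuracy",
                    ylab = "w * accuracy + (1 - w) * RPPS", ...)
  graphics::legend("bottomright", legend = x$models$name, lty = 1, lwd = 2,
                   col = seq_len(nrow(x$models)), cex = 0.8, bty = "n")
  graphics::abline(v = x$crossovers, lty = 3, col = "grey40")
  invisible(x)
}
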