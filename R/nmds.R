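#' Non-metric multidimensional scaling of a turnover matrix
#'
#' Embeds a dissimilarity matrix in `k` dimensions by minimizing Kruskal's
#' stress-1, `sqrt(sum((d - dhat)^2) / sum(d^2))`, where `d` are the
#' configuration distances and `dhat` the disparities fitted by isotonic
#' (monotone least-squares) regression on the dissimilarity ranks.  Ties in
#' the dissimilarities are handled by the primary approach: within a tie
#' block the configuration distances may take any order (the block is sorted
#' by current configuration distance before the monotone fit, which is
#' equivalent to an infinitesimal rank-space jitter of tied and zero
#' dissimilarities).
#'
#' Each restart alternates the isotonic fit with a Guttman (SMACOF majorizing)
#' update of the coordinates, with backtracking so that the recorded stress
#' trace is non-increasing; the best of `restarts` random starts plus one
#' classical-scaling (metric) start is returned.  The final configuration is
#' centred and rotated to its principal axes.
#'
#' @param d symmetric dissimilarity matrix or `dist`.
#' @param k embedding dimension (default 2); must satisfy `k < n`.
#' @param restarts number of random starts in addition to the metric start.
#' @param max_iter maximum iterations per restart.
#' @param tol relative stress-change convergence tolerance.
#' @param seed optional integer seed for the random starts.
#' @return Object of class `"nmds"`: `scores` (n x k, centred,
#'   principal-axis orientation, columns `NMDS1`, ...), `stress`,
#'   `stress_quality`, `n_restarts`, `best_start` (`0` = metric start),
#'   `converged`, and `trace` (list of per-iteration stress vectors, one per
#'   start).
#' @export
nmds <- function(d, k = 2, restarts = 20, max_iter = 500, tol = 1e-7,
                 seed = NULL) {
  D <- unclass(as.matrix(d))
  n <- nrow(D)
  if (k >= n) stop("'k' must be smaller than the number of objects (", n, ")")
  if (anyNA(D)) stop("dissimilarity matrix contains NA")
  lower <- lower.tri(D)
  diss <- D[lower]
  if (length(unique(round(diss, 12))) == 1L)
    warning("all dissimilarities are equal; the NMDS solution is degenerate")

  run_start <- function(X) {
    trace <- numeric(0)
    prev <- Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      E <- as.matrix(dist(X))
      e <- E[lower]
      ord <- order(diss, e)             # primary tie treatment
      yhat <- numeric(length(e))
      yhat[ord] <- isoreg(e[ord])$yf
      denom <- sum(e^2)
      # a collapsed configuration only has zero stress if the data are constant
      s <- if (denom > 0) sqrt(sum((e - yhat)^2) / denom)
           else if (all(diss == diss[1])) 0 else Inf
      if (s > prev + 1e-12) {           # backtrack: keep previous config
        X <- X_prev
        break
      }
      trace <- c(trace, s)
      if (is.finite(prev) && (prev - s) < tol * max(prev, .Machine$double.eps)) {
        converged <- TRUE
        prev <- s
        break
      }
      prev <- s
      X_prev <- X
      # Guttman transform with the fitted disparities
      ratio <- matrix(0, n, n)
      ratio[lower] <- ifelse(e > 1e-12, yhat / e, 0)
      ratio <- ratio + t(ratio)
      B <- -ratio
      diag(B) <- rowSums(ratio)
      X <- B %*% X / n
    }
    list(X = X, stress = prev, trace = trace, converged = converged)
  }

  starts <- with_seed(seed, {
    metric <- suppressWarnings(cmdscale(D, k = k))
    if (ncol(metric) < k)
      metric <- cbind(metric, matrix(0, n, k - ncol(metric)))
    c(list(metric),
      lapply(seq_len(restarts),
             function(i) matrix(runif(n * k, -0.5, 0.5), n, k)))
  })
  fits <- lapply(starts, run_start)
  stresses <- vapply(fits, `[[`, numeric(1), "stress")
  best <- which.min(stresses)
  X <- fits[[best]]$X
  X <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(X)
  X <- X %*% sv$v
  dimnames(X) <- list(rownames(D), paste0("NMDS", seq_len(k)))
  structure(list(scores = X, stress = stresses[best],
                 stress_quality = stress_quality(stresses[best]),
                 n_restarts = restarts, best_start = best - 1L,
                 converged = fits[[best]]$converged,
                 trace = lapply(fits, `[[`, "trace")),
            class = "nmds")
}

#' Qualitative interpretation of a stress value
#'
#' Standard reading of Kruskal's stress-1: values of 0.1 or less indicate an
#' excellent low-dimensional representation, up to 0.2 a good one, below 0.3
#' a fair one, and 0.3 or more a poor one.
#'
#' @param stress non-negative stress value.
#' @return One of `"excellent"`, `"good"`, `"fair"`, `"poor"`.
#' @export
stress_quality <- function(stress) {
  stopifnot_scalar_number(stress, "stress")
  if (stress < 0) stop("'stress' must be non-negative")
  if (stress <= 0.1) "excellent"
  else if (stress <= 0.2) "good"
  else if (stress < 0.3) "fair"
  else "poor"
}

#' @export
print.nmds <- function(x, ...) {
  cat("Non-metric multidimensional scaling\n")
  cat(sprintf("  %d points in %d dimensions; stress-1 = %.4f (%s)\n",
              nrow(x$scores), ncol(x$scores), x$stress, x$stress_quality))
  cat("  best of", x$n_restarts + 1, "starts:",
      if (x$best_start == 0) "metric (classical-scaling) start"
      else paste("random start", x$best_start),
      if (x$converged) "(converged)" else "(iteration limit)", "\n")
  invisible(x)
}

#' @export
scores <- function(object, ...) UseMethod("scores")

#' @export
scores.nmds <- function(object, ...) object$scores

#' @export
plot.nmds <- function(x, assignment = NULL, ...) {
  col <- "grey20"; pch <- 19
  if (!is.null(assignment)) {
    dd <- stats::setNames(assignment$district, assignment$cell_id)[rownames(x$scores)]
    f <- factor(dd)
    col <- hcl.colors(nlevels(f), "Dark 3")[f]
    pch <- c(19, 17, 15, 18)[(as.integer(f) - 1L) %% 4L + 1L]
  }
  plot(x$scores[, 1], x$scores[, 2], col = col, pch = pch,
       xlab = "NMDS1", ylab = "NMDS2",
       main = sprintf("NMDS (stress = %.3f)", x$stress), ...)
  invisible(x)
}

#' Per-axis cell score tables with a fixed sign convention
#'
#' Extracts one `(cell_id, score)` table per ordination axis, with each
#' axis's sign fixed so that the first district (by label sort) has a
#' non-negative mean score.  The convention makes exports invariant to the
#' arbitrary reflection of NMDS axes.
#'
#' @param ordination an [nmds()] fit.
#' @param assignment a [consolidate_districts()] region assignment covering
#'   the ordinated cells.
#' @return List of class `"axis_maps"`: `tables` (one data frame per axis)
#'   and `scores` (the sign-fixed score matrix).
#' @export
axis_maps <- function(ordination, assignment) {
  stopifnot(inherits(ordination, "nmds"))
  sc <- ordination$scores
  dd <- stats::setNames(assignment$district, assignment$cell_id)
  if (!all(rownames(sc) %in% names(dd)))
    stop("assignment does not cover all ordinated cells")
  dd <- dd[rownames(sc)]
  ref <- sort(unique(dd))[1]
  for (j in seq_len(ncol(sc))) {
    if (mean(sc[dd == ref, j]) < 0) sc[, j] <- -sc[, j]
  }
  tables <- lapply(seq_len(ncol(sc)), function(j) {
    data.frame(cell_id = rownames(sc), score = unname(sc[, j]),
               stringsAsFactors = FALSE)
  })
  names(tables) <- colnames(sc)
  structure(list(tables = tables, scores = sc), class = "axis_maps")
}
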