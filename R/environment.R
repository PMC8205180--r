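#' Aggregate environmental pixels to grid cells
#'
#' Cell value = arithmetic mean of the pixels whose centres fall in the cell,
#' using the same half-open cell rule as [assign_to_grid()].
#'
#' @param pixels data frame with `lon`, `lat` and one numeric column per
#'   variable.
#' @param grid a [grid_spec()]; a `NULL` origin snaps to the pixel extent.
#' @param cells optional character vector of required cell ids; cells with no
#'   pixel coverage are excluded with a warning and listed in the
#'   `"missing_cells"` attribute.
#' @return Data frame `cell_id` + per-variable cell means, sorted by cell id.
#' @export
aggregate_pixels <- function(pixels, grid = grid_spec(), cells = NULL) {
  stopifnot(is.data.frame(pixels), all(c("lon", "lat") %in% names(pixels)))
  vars <- setdiff(names(pixels), c("lon", "lat"))
  if (!length(vars)) stop("no variable columns in 'pixels'")
  origin <- grid$origin %||%
    c(floor(min(pixels$lon) / grid$cell_size) * grid$cell_size,
      floor(min(pixels$lat) / grid$cell_size) * grid$cell_size)
  ix <- cell_index(pixels$lon, origin[1], grid$cell_size)
  iy <- cell_index(pixels$lat, origin[2], grid$cell_size)
  id <- sprintf("c%03d_%03d", ix, iy)
  out <- aggregate(pixels[vars], by = list(cell_id = id), FUN = mean)
  out <- out[order(out$cell_id), ]
  rownames(out) <- NULL
  if (!is.null(cells)) {
    missing <- setdiff(cells, out$cell_id)
    if (length(missing))
      warning(length(missing), " cell(s) with no pixel coverage excluded: ",
              paste(head(missing, 5), collapse = ", "),
              if (length(missing) > 5) ", ...")
    out <- out[out$cell_id %in% cells, ]
    rownames(out) <- NULL
    attr(out, "missing_cells") <- missing
  }
  out
}

env_values <- function(env) {
  # split an env table into its numeric matrix + cell ids
  if (is.matrix(env)) return(list(m = env, id = rownames(env)))
  id <- if ("cell_id" %in% names(env)) env$cell_id else rownames(env)
  m <- as.matrix(env[setdiff(names(env), "cell_id")])
  rownames(m) <- id
  list(m = m, id = id)
}

#' Prune collinear environmental variables
#'
#' Greedy Pearson-correlation pruning: while any variable pair exceeds the
#' absolute-correlation threshold, the member of the worst pair with the
#' larger mean absolute correlation to all remaining variables is dropped
#' (ties: the later column).  Constant columns are dropped first.
#'
#' @param env environmental table (`cell_id` + numeric columns, or a matrix).
#' @param threshold absolute Pearson correlation above which a pair is
#'   considered collinear (default 0.8).
#' @return List of class `"pruned_env"`: `env` (the reduced table) and
#'   `dropped`, a data frame reporting every drop with the triggering pair
#'   and its correlation.
#' @export
prune_collinear <- function(env, threshold = 0.8) {
  ev <- env_values(env)
  m <- ev$m
  if (ncol(m) < 2L) stop("need at least 2 variables")
  if (nrow(m) < 3L) stop("need at least 3 cells")
  dropped <- data.frame(dropped = character(0), against = character(0),
                        r = numeric(0), reason = character(0),
                        stringsAsFactors = FALSE)
  sds <- apply(m, 2, sd)
  for (v in colnames(m)[sds == 0]) {
    dropped <- rbind(dropped, data.frame(dropped = v, against = NA_character_,
                                         r = NA_real_, reason = "constant"))
  }
  m <- m[, sds > 0, drop = FALSE]
  repeat {
    if (ncol(m) < 2L) break
    r <- abs(cor(m))
    diag(r) <- 0
    if (max(r) <= threshold) break
    worst <- which(r == max(r), arr.ind = TRUE)[1, ]
    v1 <- colnames(m)[worst[1]]; v2 <- colnames(m)[worst[2]]
    mean_r <- colMeans(r)[c(v1, v2)]
    drop <- if (mean_r[1] > mean_r[2]) v1
            else if (mean_r[2] > mean_r[1]) v2
            else c(v1, v2)[max(match(c(v1, v2), colnames(m))) == match(c(v1, v2), colnames(m))]
    keep_of_pair <- setdiff(c(v1, v2), drop)
    dropped <- rbind(dropped, data.frame(dropped = drop, against = keep_of_pair,
                                         r = max(r), reason = "collinear"))
    m <- m[, colnames(m) != drop, drop = FALSE]
  }
  out <- data.frame(cell_id = ev$id, m, stringsAsFactors = FALSE,
                    check.names = FALSE)
  rownames(out) <- NULL
  structure(list(env = out, dropped = dropped), class = "pruned_env")
}

#' @export
print.pruned_env <- function(x, ...) {
  cat("Collinearity pruning:", ncol(x$env) - 1L, "variables retained,",
      nrow(x$dropped), "dropped\n")
  if (nrow(x$dropped)) print(x$dropped)
  invisible(x)
}

#' Standardize an environmental table to z-scores
#'
#' Each column is centred and scaled by its sample standard deviation
#' (`n - 1` denominator).  Column means and sds are stored as attributes so
#' the transform is invertible with [unstandardize_env()].
#'
#' @param env environmental table (`cell_id` + numeric columns, or matrix).
#' @return The standardized table with attributes `"center"`, `"scale"` and
#'   `"standardized" = TRUE`.
#' @export
standardize_env <- function(env) {
  ev <- env_values(env)
  sds <- apply(ev$m, 2, sd)
  if (any(sds == 0))
    stop("constant column(s): ", paste(colnames(ev$m)[sds == 0], collapse = ", "),
         "; prune before standardizing")
  ctr <- colMeans(ev$m)
  z <- sweep(sweep(ev$m, 2, ctr), 2, sds, "/")
  out <- data.frame(cell_id = ev$id, z, stringsAsFactors = FALSE,
                    check.names = FALSE)
  rownames(out) <- NULL
  attr(out, "center") <- ctr
  attr(out, "scale") <- sds
  attr(out, "standardized") <- TRUE
  out
}

#' @rdname standardize_env
#' @export
unstandardize_env <- function(env) {
  ctr <- attr(env, "center"); scl <- attr(env, "scale")
  if (is.null(ctr) || is.null(scl)) stop("not a standardize_env() result")
  ev <- env_values(env)
  m <- sweep(sweep(ev$m, 2, scl, "*"), 2, ctr, "+")
  out <- data.frame(cell_id = ev$id, m, stringsAsFactors = FALSE,
                    check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Redundancy analysis (constrained variance decomposition)
#'
#' Regresses every response column on the predictors by least squares; the
#' canonical (constrained) variance is the total variance of the fitted
#' values, and the proportion explained is the redundancy statistic
#' `tr(Yhat' Yhat) / tr(Y' Y)` on column-centred matrices.  Canonical axes
#' are the principal axes of the fitted values.
#'
#' @param Y response matrix (cells x species), typically a z-scored incidence
#'   matrix.
#' @param X predictor matrix or data frame (cells x variables), typically
#'   z-scored.
#' @return Object of class `"rda_fit"`: `proportion_explained`,
#'   `canonical_variance`, `total_variance`, `eigenvalues` (canonical),
#'   `rank`, `n`.
#' @export
rda_fit <- function(Y, X) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  if (nrow(Y) != nrow(X)) stop("Y and X must have the same number of rows")
  n <- nrow(Y)
  if (n <= ncol(X)) stop("need more observations than predictors")
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  qx <- qr(Xc)
  if (qx$rank < ncol(Xc)) {
    dep <- colnames(Xc)[qx$pivot[(qx$rank + 1):ncol(Xc)]]
    stop("rank-deficient predictors; linearly dependent column(s): ",
         paste(dep, collapse = ", "))
  }
  Yhat <- qr.fitted(qx, Yc)
  canonical <- sum(Yhat^2) / (n - 1)
  total <- sum(Yc^2) / (n - 1)
  ev <- svd(Yhat, nu = 0, nv = 0)$d^2 / (n - 1)
  ev <- ev[ev > max(ev) * 1e-12]
  structure(list(proportion_explained = canonical / total,
                 canonical_variance = canonical, total_variance = total,
                 eigenvalues = ev, rank = qx$rank, n = n),
            class = "rda_fit")
}

#' @export
print.rda_fit <- function(x, ...) {
  cat("Redundancy analysis\n")
  cat(sprintf("  constrained variance: %.4f of %.4f total (%.2f%%)\n",
              x$canonical_variance, x$total_variance,
              100 * x$proportion_explained))
  cat("  canonical eigenvalues:",
      paste(format(head(x$eigenvalues, 5), digits = 4), collapse = ", "),
      if (length(x$eigenvalues) > 5) "...", "\n")
  invisible(x)
}

#' Permutation-based forward selection of environmental predictors
#'
#' Builds the most parsimonious constrained-ordination model stepwise.  At
#' each step every unused variable is scored by the Gaussian-likelihood AIC
#' of the multivariate fit (`n * log(RSS/n) + 2 * (p + 1)`, a ranking
#' statistic over the total residual sum of squares) and by its marginal
#' pseudo-F; the best candidate is admitted if its permutation p-value is at
#' most `alpha`.  The permutation null permutes the response rows and uses
#' the *maximum* pseudo-F over the remaining candidates, so the step-wise
#' p-value accounts for selecting the best of many candidates and the
#' admission rate under a pure-noise predictor set is calibrated at `alpha`.
#'
#' @param Y response matrix (cells x species; z-scored incidence).
#' @param X candidate predictor table (`cell_id` column allowed) or matrix.
#' @param permutations permutations per step (default 999).
#' @param alpha admission threshold on the permutation p-value.
#' @param stop_rule `"alpha"` (permutation test, default) or `"aic"`
#'   (admit while the AIC improves; no permutations, p-values `NA`).
#' @param max_steps maximum number of variables to admit.
#' @param seed optional integer seed.
#' @return Object of class `"forward_selection"`: `steps` (data frame
#'   `variable`, `df`, `AIC`, `F`, `p_value` for each accepted step),
#'   `selected`, `proportion_explained` (of the final model), `permutations`,
#'   `alpha`, `n`.
#' @export
forward_select <- function(Y, X, permutations = 999, alpha = 0.05,
                           stop_rule = c("alpha", "aic"),
                           max_steps = Inf, seed = NULL) {
  stop_rule <- match.arg(stop_rule)
  Y <- as.matrix(Y)
  ev <- env_values(X)
  Xm <- ev$m
  if (!is.null(ev$id) && !is.null(rownames(Y)) &&
      all(rownames(Y) %in% ev$id)) {
    Xm <- Xm[match(rownames(Y), ev$id), , drop = FALSE]
  }
  if (nrow(Y) != nrow(Xm)) stop("Y and X must cover the same cells")
  n <- nrow(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xc <- scale(Xm, center = TRUE, scale = FALSE)
  tot_ss <- sum(Yc^2)
  vars <- colnames(Xc)
  steps <- data.frame(variable = character(0), df = integer(0),
                      AIC = numeric(0), F = numeric(0), p_value = numeric(0),
                      stringsAsFactors = FALSE)
  Q <- matrix(0, n, 0)
  rss <- tot_ss
  unused <- vars
  with_seed(seed, {
    while (length(unused) > 0 && nrow(steps) < max_steps) {
      if (rss <= tot_ss * 1e-12) break   # model already saturated
      p_new <- ncol(Q) + 1L
      df2 <- n - p_new - 1L
      if (df2 < 1L) break
      # residualize candidates against current model, normalize
      Qs <- Xc[, unused, drop = FALSE]
      if (ncol(Q) > 0) Qs <- Qs - Q %*% (t(Q) %*% Qs)
      norms <- sqrt(colSums(Qs^2))
      ok <- norms > sqrt(.Machine$double.eps) * sqrt(n)
      if (!any(ok)) break
      Qs <- sweep(Qs[, ok, drop = FALSE], 2, norms[ok], "/")
      cand <- unused[ok]
      add_ss <- rowSums((t(Qs) %*% Yc)^2)
      rss_after <- pmax(rss - add_ss, 0)   # clamp numerical noise at a perfect fit
      f_obs <- (add_ss / 1) / (rss_after / df2)
      aic <- n * log(rss_after / n) + 2 * (p_new + 1)
      best <- which.min(aic)   # lowest AIC == largest added SS == largest F
      p_val <- NA_real_
      if (stop_rule == "alpha") {
        qq <- cbind(Q, Qs)
        f_best <- f_obs[best]
        exceed <- 0L
        for (b in seq_len(permutations)) {
          Yp <- Yc[sample.int(n), , drop = FALSE]
          A <- t(qq) %*% Yp
          fit_cur <- if (ncol(Q) > 0) sum(A[seq_len(ncol(Q)), ]^2) else 0
          rss_p <- tot_ss - fit_cur
          add_p <- rowSums(A[ncol(Q) + seq_along(cand), , drop = FALSE]^2)
          f_p <- max((add_p / 1) / ((rss_p - add_p) / df2))
          if (f_p >= f_best) exceed <- exceed + 1L
        }
        p_val <- (exceed + 1) / (permutations + 1)
        if (p_val > alpha) break
      } else {
        aic_cur <- n * log(rss / n) + 2 * (p_new)
        if (aic[best] >= aic_cur) break
      }
      steps[nrow(steps) + 1L, ] <- list(cand[best], 1L, aic[best],
                                        f_obs[best], p_val)
      Q <- cbind(Q, Qs[, best, drop = FALSE])
      rss <- rss_after[best]
      unused <- setdiff(unused, cand[best])
    }
  })
  if (nrow(steps) == 0L)
    warning("no variable admitted at alpha = ", alpha)
  prop <- if (nrow(steps)) (tot_ss - rss) / tot_ss else 0
  structure(list(steps = steps, selected = steps$variable,
                 proportion_explained = prop,
                 permutations = if (stop_rule == "alpha") permutations else 0L,
                 alpha = alpha, stop_rule = stop_rule, n = n),
            class = "forward_selection")
}

#' @export
print.forward_selection <- function(x, ...) {
  cat("Forward selection of environmental predictors (",
      if (x$stop_rule == "alpha")
        sprintf("permutation stop, alpha = %g, %d permutations",
                x$alpha, x$permutations)
      else "AIC stop", ")\n", sep = "")
  if (nrow(x$steps) == 0L) {
    cat("  no variable admitted\n")
    return(invisible(x))
  }
  st <- x$steps
  stars <- ifelse(is.na(st$p_value), "",
                  ifelse(st$p_value <= 0.001, "***",
                         ifelse(st$p_value <= 0.01, "**",
                                ifelse(st$p_value <= 0.05, "*", ""))))
  out <- data.frame(Df = st$df, AIC = round(st$AIC, 2),
                    F = round(st$F, 4),
                    `Pr(>F)` = st$p_value, sig = stars,
                    row.names = st$variable, check.names = FALSE)
  print(out)
  cat(sprintf("model explains %.2f%% of total variance\n",
              100 * x$proportion_explained))
  invisible(x)
}
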