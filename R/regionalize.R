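#' WPGMA hierarchical clustering of a turnover matrix
#'
#' Weighted pair-group clustering with arithmetic mean (McQuitty linkage): at
#' each step the pair of clusters at minimal distance is merged, and the
#' distance from the new cluster to any other is the plain average of the two
#' merged clusters' distances, so each of the two merged groups contributes
#' equally regardless of its size.
#'
#' @param d a symmetric dissimilarity matrix (e.g. [turnover_matrix()]) or a
#'   `dist` object; must be free of `NA`/`NaN`.
#' @return An object of classes `"wpgma"` and `"hclust"` (so [stats::cutree()]
#'   and `plot()` work as usual).
#' @export
wpgma <- function(d) {
  dd <- if (inherits(d, "dist")) d else as.dist(unclass(as.matrix(d)))
  if (anyNA(dd)) stop("dissimilarity matrix contains NA/NaN")
  if (attr(dd, "Size") < 2L) stop("need at least 2 observations")
  h <- hclust(dd, method = "mcquitty")
  class(h) <- c("wpgma", "hclust")
  h
}

#' Cut a dendrogram into k groups
#'
#' Removes the `k - 1` highest merges, leaving `k` connected groups.
#'
#' @param dendrogram a [wpgma()] (or any `hclust`) tree.
#' @param k number of groups, `1 <= k <= n`.
#' @return Named integer vector of group memberships (names = cell ids).
#' @export
cut_groups <- function(dendrogram, k) {
  stopifnot(inherits(dendrogram, "hclust"))
  n <- length(dendrogram$labels %||% dendrogram$order)
  if (k < 1L || k > n) stop("'k' must be between 1 and ", n)
  cutree(dendrogram, k = k)
}

#' Consolidate cluster groups into final districts
#'
#' The `k_final` largest groups (by cell count) become districts; every cell
#' of a minor group is reassigned to the district whose members it joins at
#' the lowest dendrogram height, i.e. minimal cophenetic distance.  This is
#' the "reassign under-represented groups" step between the raw dendrogram
#' cut and the final regionalization.
#'
#' @param groups named group vector from [cut_groups()].
#' @param dendrogram the tree the groups were cut from.
#' @param k_final number of final districts (default 2).
#' @return A data frame of class `"region_assignment"` with columns
#'   `cell_id`, `district` (labels `"D1"`, `"D2"`, ... in decreasing size
#'   order of the founding groups) and `provenance` (`"cluster"` for members
#'   of a major group, `"reassigned"` otherwise).
#' @export
consolidate_districts <- function(groups, dendrogram, k_final = 2) {
  stopifnot(inherits(dendrogram, "hclust"))
  sizes <- table(groups)
  if (length(sizes) < k_final)
    stop("only ", length(sizes), " groups but k_final = ", k_final)
  rank_ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  major <- names(sizes)[rank_ord[seq_len(k_final)]]
  district_of_group <- stats::setNames(sprintf("D%d", seq_len(k_final)), major)
  ids <- names(groups)
  district <- unname(district_of_group[as.character(groups)])
  provenance <- ifelse(is.na(district), "reassigned", "cluster")
  if (any(is.na(district))) {
    coph <- as.matrix(cophenetic(dendrogram))[ids, ids, drop = FALSE]
    minor_idx <- which(is.na(district))
    for (i in minor_idx) {
      h_to_major <- vapply(major, function(g) {
        min(coph[i, groups == as.integer(g)])
      }, numeric(1))
      district[i] <- district_of_group[major[which.min(h_to_major)]]
    }
  }
  out <- data.frame(cell_id = ids, district = district,
                    provenance = provenance, stringsAsFactors = FALSE)
  class(out) <- c("region_assignment", class(out))
  out
}

#' Multi-response permutation procedure
#'
#' Tests whether within-group dissimilarity is smaller than expected under
#' random relabelling.  The observed statistic is the weighted mean of
#' per-group mean pairwise dissimilarities, `delta = sum_g (n_g / N) xi_g`;
#' the null distribution permutes group labels holding group sizes fixed, and
#' the test is one-sided towards small `delta` (homogeneous groups).  The
#' chance-corrected within-group agreement is
#' `A = 1 - delta_obs / mean(delta_perm)`.
#'
#' @param d symmetric dissimilarity matrix or `dist`.
#' @param grouping group label per observation (length n, >= 2 groups, every
#'   group with >= 2 members).
#' @param permutations number of random label permutations (default 999).
#' @param seed optional integer seed for the permutations.
#' @return Object of class `"mrpp_test"`: `observed_delta`, `group_stats`
#'   (group, n, xi, weight), `p_value`, `A`, `permutations`, `delta_perm`.
#' @export
mrpp_test <- function(d, grouping, permutations = 999, seed = NULL) {
  D <- unclass(as.matrix(d))
  grouping <- stats::setNames(as.character(grouping), names(grouping))
  n <- nrow(D)
  if (length(grouping) != n) stop("'grouping' length must match matrix size")
  if (!is.null(rownames(D)) && !is.null(names(grouping)) &&
      all(rownames(D) %in% names(grouping)))
    grouping <- grouping[rownames(D)]
  tab <- table(grouping)
  if (length(tab) < 2L) stop("need at least 2 groups")
  if (any(tab < 2L)) stop("every group needs >= 2 members; too small: ",
                          paste(names(tab)[tab < 2], collapse = ", "))
  if (permutations < 1L) stop("'permutations' must be >= 1")
  delta_of <- function(lab) {
    s <- 0
    for (g in names(tab)) {
      i <- which(lab == g)
      ng <- length(i)
      s <- s + (ng / n) * (sum(D[i, i]) / (ng * (ng - 1)))
    }
    s
  }
  xi <- vapply(names(tab), function(g) {
    i <- which(grouping == g)
    sum(D[i, i]) / (length(i) * (length(i) - 1))
  }, numeric(1))
  observed <- sum((tab / n) * xi)
  delta_perm <- with_seed(seed, {
    vapply(seq_len(permutations),
           function(k) delta_of(sample(grouping)), numeric(1))
  })
  p <- (sum(delta_perm <= observed) + 1) / (permutations + 1)
  structure(list(
    observed_delta = observed,
    group_stats = data.frame(group = names(tab), n = as.integer(tab),
                             xi = unname(xi), weight = as.numeric(tab / n),
                             stringsAsFactors = FALSE),
    permutations = permutations, p_value = p,
    A = 1 - observed / mean(delta_perm),
    delta_perm = delta_perm
  ), class = "mrpp_test")
}

#' @export
print.mrpp_test <- function(x, digits = 4, ...) {
  cat("Multi-response permutation procedure\n")
  cat("  observed delta:", format(x$observed_delta, digits = digits),
      " expected:", format(mean(x$delta_perm), digits = digits), "\n")
  cat("  chance-corrected agreement A:", format(x$A, digits = digits), "\n")
  cat("  significance (", x$permutations, " permutations): p = ",
      format(x$p_value, digits = digits), "\n", sep = "")
  invisible(x)
}

#' Delimit biogeographic districts from species composition
#'
#' The central fit of the package: computes the beta-Simpson turnover matrix,
#' clusters cells by WPGMA, cuts the tree into `k_groups` compositional
#' groups, consolidates them into the `k_final` largest districts (minor
#' groups reassigned by cophenetic proximity), and validates the final
#' districts with an MRPP permutation test.
#'
#' @param x a [grid_occurrences()] cell table, a cell-by-species 0/1
#'   incidence matrix, or a precomputed dissimilarity
#'   ([turnover_matrix()] result or `dist`).
#' @param k_groups number of compositional groups to cut (default 8).
#' @param k_final number of final districts (default 2).
#' @param permutations MRPP permutations (default 999).
#' @param seed optional seed for the MRPP permutations.
#' @return Object of class `"regionalization"` with components `turnover`,
#'   `dendrogram`, `groups`, `assignment`, `mrpp`, `k_groups`, `k_final`,
#'   and `cells` (geometry, when `x` was a cell table).  Methods:
#'   `print()`, `summary()`, `plot()`, [districts()].
#' @examples
#' ls <- generate_landscape(landscape_spec(), seed = 1)
#' occ <- generate_occurrences(ls, community_spec(seed = 1))
#' ct <- grid_occurrences(occ, grid_spec(origin = ls$spec$extent[c(1, 3)]))
#' rg <- regionalize(ct, k_groups = 8, k_final = 2, permutations = 99, seed = 1)
#' print(rg)
#' @export
regionalize <- function(x, k_groups = 8, k_final = 2, permutations = 999,
                        seed = NULL) {
  cells <- NULL
  if (inherits(x, "cell_table")) {
    cells <- x$cells
    d <- turnover_matrix(incidence_matrix(x))
  } else if (inherits(x, "beta_sim_matrix") || inherits(x, "dist")) {
    d <- unclass(as.matrix(x))
  } else if (is.matrix(x)) {
    is_square_sym <- nrow(x) == ncol(x) && isTRUE(all.equal(unname(x), unname(t(x)))) &&
      all(diag(x) == 0)
    d <- if (is_square_sym && !all(x %in% c(0, 1))) unclass(x)
         else turnover_matrix(x)
  } else stop("'x' must be a cell_table, incidence matrix or dissimilarity")
  h <- wpgma(d)
  k_groups <- min(k_groups, nrow(as.matrix(d)))
  groups <- cut_groups(h, k_groups)
  assignment <- consolidate_districts(groups, h, k_final = k_final)
  grp <- stats::setNames(assignment$district, assignment$cell_id)
  mrpp <- mrpp_test(d, grp, permutations = permutations, seed = seed)
  structure(list(turnover = d, dendrogram = h, groups = groups,
                 assignment = assignment, mrpp = mrpp, cells = cells,
                 k_groups = k_groups, k_final = k_final,
                 call = match.call()),
            class = "regionalization")
}

#' District membership of a regionalization
#'
#' @param object a `"regionalization"` fit.
#' @return Named character vector: cell id -> district label.
#' @export
districts <- function(object) {
  stopifnot(inherits(object, "regionalization"))
  stats::setNames(object$assignment$district, object$assignment$cell_id)
}

#' @export
print.regionalization <- function(x, ...) {
  cat("Biogeographic regionalization (beta-Simpson + WPGMA)\n")
  cat("  cells:", nrow(x$assignment), "  groups cut:", x$k_groups,
      "  districts:", x$k_final, "\n")
  tab <- table(x$assignment$district)
  cat("  district sizes:", paste(sprintf("%s=%d", names(tab), tab),
                                 collapse = ", "), "\n")
  nr <- sum(x$assignment$provenance == "reassigned")
  if (nr) cat("  reassigned from minor groups:", nr, "cells\n")
  cat(sprintf("  MRPP: delta = %.4f, A = %.4f, p = %.4g (%d permutations)\n",
              x$mrpp$observed_delta, x$mrpp$A, x$mrpp$p_value,
              x$mrpp$permutations))
  invisible(x)
}

#' @export
summary.regionalization <- function(object, ...) {
  cat("Group sizes at k =", object$k_groups, "cut:\n")
  print(table(object$groups))
  cat("\nFinal districts:\n")
  print(table(object$assignment$district, object$assignment$provenance))
  cat("\n")
  print(object$mrpp)
  invisible(object)
}

#' @export
plot.regionalization <- function(x, which = c("dendrogram", "map"), ...) {
  which <- match.arg(which)
  if (which == "dendrogram") {
    plot(x$dendrogram, labels = FALSE, hang = -1,
         main = "WPGMA on beta-Simpson turnover", xlab = "", sub = "",
         ylab = "dissimilarity", ...)
    stats::rect.hclust(x$dendrogram, k = x$k_final,
                       border = hcl.colors(x$k_final, "Dark 3"))
  } else {
    if (is.null(x$cells)) stop("no cell geometry stored; fit on a cell_table")
    cells <- merge(x$cells, x$assignment, by = "cell_id")
    cols <- hcl.colors(x$k_final, "Dark 3")[factor(cells$district)]
    plot(NA, xlim = range(cells$lon_min, cells$lon_max),
         ylim = range(cells$lat_min, cells$lat_max),
         xlab = "longitude", ylab = "latitude", asp = 1,
         main = "Districts", ...)
    rect(cells$lon_min, cells$lat_min, cells$lon_max, cells$lat_max,
         col = cols, border = "grey30")
  }
  invisible(x)
}
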