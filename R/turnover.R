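#' Beta-Simpson dissimilarity between two species sets
#'
#' The spatial-turnover component of beta diversity:
#' `1 - a / (a + min(b, c))`, where `a` is the number of shared species, `b`
#' the number found only in the first set and `c` only in the second.  The
#' `min(b, c)` term makes the index insensitive to richness imbalance: a
#' perfectly nested pair scores 0 regardless of the richness difference,
#' while fully disjoint sets score 1.
#'
#' @param set_i,set_j character vectors of species names (duplicates
#'   ignored); at least one must be non-empty.  An empty set against a
#'   non-empty one shares nothing and scores 1 (the `a = 0` limit); both sets
#'   empty is undefined (0/0) and raises an error.
#' @return Dissimilarity in `[0, 1]`.
#' @examples
#' beta_sim(c("x", "y", "z"), c("x", "y"))          # nested: 0
#' beta_sim(letters[1:3], letters[4:6])              # disjoint: 1
#' @export
beta_sim <- function(set_i, set_j) {
  set_i <- unique(set_i); set_j <- unique(set_j)
  if (length(set_i) == 0L && length(set_j) == 0L)
    stop("beta_sim is undefined for two empty species sets (0/0)")
  a <- length(intersect(set_i, set_j))
  b <- length(setdiff(set_i, set_j))
  c_ <- length(setdiff(set_j, set_i))
  denom <- a + min(b, c_)
  if (denom == 0 && a == 0) return(1)  # one set empty: nothing shared
  1 - a / denom
}

#' Pairwise beta-Simpson turnover matrix
#'
#' Computes [beta_sim()] for every pair of rows of an incidence matrix using
#' incidence linear algebra (shared counts from a cross-product, `b`/`c` from
#' row sums), which is exactly equivalent to the set definition.
#'
#' @param incidence cell-by-species 0/1 matrix with row names (see
#'   [incidence_matrix()]); every row must contain at least one species.
#' @return Symmetric numeric matrix of class `"beta_sim_matrix"` with zero
#'   diagonal, labelled by the incidence row names.
#' @export
turnover_matrix <- function(incidence) {
  m <- as.matrix(incidence)
  if (nrow(m) < 2L) stop("need at least 2 cells")
  storage.mode(m) <- "double"
  rs <- rowSums(m)
  if (any(rs == 0)) {
    bad <- rownames(m)[rs == 0] %||% which(rs == 0)
    stop("cell(s) with zero species: ", paste(bad, collapse = ", "))
  }
  a <- tcrossprod(m)                       # shared species counts
  b <- matrix(rs, nrow(m), nrow(m)) - a    # b[i, j] = |i \ j|
  d <- 1 - a / (a + pmin(b, t(b)))
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  class(d) <- c("beta_sim_matrix", class(d))
  d
}

#' @export
print.beta_sim_matrix <- function(x, ...) {
  v <- x[upper.tri(x)]
  cat("beta-Simpson turnover matrix:", nrow(x), "cells\n",
      sprintf(" range %.3f-%.3f, mean %.3f\n", min(v), max(v), mean(v)))
  invisible(x)
}

#' Write / read a labelled square distance matrix as CSV
#'
#' Plain interchange format: a header row of cell ids and one labelled row
#' per cell.
#'
#' @param d symmetric labelled matrix.
#' @param path file path.
#' @return `read_dist_csv` returns the matrix (class `"beta_sim_matrix"`).
#' @export
write_dist_csv <- function(d, path) {
  write.csv(as.data.frame(unclass(d)), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_dist_csv
#' @export
read_dist_csv <- function(path) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  d <- as.matrix(df)
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(rownames(d), colnames(d))))
    stop("not a labelled square matrix: ", path)
  class(d) <- c("beta_sim_matrix", class(d))
  d
}
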