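# Independent oracle implementations used across the suite.  These are kept
# deliberately naive (explicit sets, O(n^3) loops, exhaustive enumeration) so
# they stay independent of the package's vectorized code paths.

# set-algebra beta-Simpson for two 0/1 rows
oracle_beta_sim <- function(row_i, row_j) {
  si <- names(row_i)[row_i > 0]
  sj <- names(row_j)[row_j > 0]
  a <- length(intersect(si, sj))
  b <- length(setdiff(si, sj))
  cc <- length(setdiff(sj, si))
  1 - a / (a + min(b, cc))
}

oracle_turnover_matrix <- function(inc) {
  n <- nrow(inc)
  out <- matrix(0, n, n, dimnames = list(rownames(inc), rownames(inc)))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    out[i, j] <- oracle_beta_sim(inc[i, ], inc[j, ])
  out
}

# naive O(n^3) WPGMA producing hclust-style merge/height encoding
oracle_wpgma <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  id <- -(seq_len(n))          # hclust codes: negative leaf, positive merge
  act <- seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (s in seq_len(n - 1L)) {
    best <- c(Inf, 0L, 0L)
    for (i in seq_along(act)) for (j in seq_along(act)) if (i < j) {
      if (D[act[i], act[j]] < best[1]) best <- c(D[act[i], act[j]], i, j)
    }
    i <- best[2]; j <- best[3]
    merge[s, ] <- sort(c(id[act[i]], id[act[j]]))
    height[s] <- best[1]
    for (k in seq_along(act)) if (k != i && k != j) {
      newd <- (D[act[i], act[k]] + D[act[j], act[k]]) / 2
      D[act[i], act[k]] <- D[act[k], act[i]] <- newd
    }
    id[act[i]] <- s
    act <- act[-j]
  }
  list(merge = merge, height = height)
}

canonical_merge <- function(m) t(apply(m, 1, sort))

# exhaustive minimum spanning-tree length by decoding every Pruefer sequence
oracle_mst_min_length <- function(D) {
  n <- nrow(D)
  stopifnot(n >= 3, n <= 7)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  m <- nrow(seqs)
  deg <- matrix(1L, m, n)
  for (j in seq_len(n)) deg[, j] <- deg[, j] + rowSums(seqs == j)
  used <- matrix(FALSE, m, n)
  w <- matrix(rep(n:1, each = m), m, n)   # prefer the lowest column index
  total <- numeric(m)
  for (step in seq_len(n - 2L)) {
    a <- seqs[, step]
    elig <- (deg == 1L) & !used
    leaf <- max.col(elig * w, ties.method = "first")
    total <- total + D[cbind(leaf, a)]
    used[cbind(seq_len(m), leaf)] <- TRUE
    deg[cbind(seq_len(m), leaf)] <- 0L
    deg[cbind(seq_len(m), a)] <- deg[cbind(seq_len(m), a)] - 1L
  }
  elig <- (deg == 1L) & !used
  e1 <- max.col(elig * w, ties.method = "first")
  elig[cbind(seq_len(m), e1)] <- FALSE
  e2 <- max.col(elig * w, ties.method = "first")
  total <- total + D[cbind(e1, e2)]
  min(total)
}

# stress-1 of a configuration against a dissimilarity matrix, with the same
# primary tie treatment as the package (recomputed independently here)
stress1_of <- function(D, X) {
  lower <- lower.tri(D)
  diss <- D[lower]
  e <- as.matrix(dist(X))[lower]
  ord <- order(diss, e)
  yhat <- numeric(length(e))
  yhat[ord] <- isoreg(e[ord])$yf
  sqrt(sum((e - yhat)^2) / sum(e^2))
}

random_incidence <- function(n_cells, n_species, p = 0.3) {
  m <- matrix(rbinom(n_cells * n_species, 1, p), n_cells, n_species,
              dimnames = list(sprintf("c%03d", seq_len(n_cells)),
                              sprintf("sp%03d", seq_len(n_species))))
  # guarantee non-empty rows and columns
  for (i in which(rowSums(m) == 0)) m[i, sample(n_species, 1)] <- 1L
  m[, colSums(m) > 0, drop = FALSE]
}

# small planted dataset shared by several tests
planted_fixture <- function(seed = 1, effort_mean = 60) {
  ls <- generate_landscape(landscape_spec(), seed = seed)
  occ <- generate_occurrences(ls, community_spec(effort_mean = effort_mean,
                                                 seed = seed + 1))
  ct <- grid_occurrences(occ, grid_spec(origin = ls$spec$extent[c(1, 3)]))
  list(landscape = ls, occ = occ, ct = ct)
}
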