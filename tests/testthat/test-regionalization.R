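dist_matrix <- function(v, labels) {
  n <- length(labels)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[lower.tri(m)] <- v
  m + t(m)
}

test_that("wpgma handles the smallest trees and the hand-worked update", {
  d2 <- dist_matrix(0.4, c("x", "y"))
  h2 <- wpgma(d2)
  expect_equal(h2$height, 0.4)
  # d(1,2)=0.2, d(1,3)=0.6, d(2,3)=0.8: merge (1,2)@0.2, then (0.6+0.8)/2=0.7
  d3 <- dist_matrix(c(0.2, 0.6, 0.8), c("a", "b", "c"))
  h3 <- wpgma(d3)
  expect_equal(h3$height, c(0.2, 0.7))
  expect_equal(sort(h3$merge[1, ]), c(-2, -1))
  # cutting at k = 2 separates the singleton
  grp <- cut_groups(h3, 2)
  expect_equal(unname(grp[c("a", "b")]), c(1, 1))
  expect_equal(unname(grp["c"]), 2)
})

test_that("wpgma equals the naive O(n^3) oracle on random instances", {
  set.seed(21)
  for (rep in 1:30) {
    n <- sample(5:10, 1)
    D <- dist_matrix(runif(n * (n - 1) / 2), sprintf("l%02d", 1:n))
    h <- wpgma(D)
    o <- oracle_wpgma(D)
    expect_equal(h$height, o$height, tolerance = 1e-12)
    expect_equal(canonical_merge(h$merge), canonical_merge(o$merge),
                 ignore_attr = TRUE)
  }
})

test_that("wpgma rejects NaN and trivial input, cut_groups checks bounds", {
  D <- dist_matrix(c(0.2, NA, 0.8), letters[1:3])
  expect_error(wpgma(D), "NA")
  expect_error(wpgma(matrix(0, 1, 1)), "at least 2")
  d3 <- dist_matrix(c(0.2, 0.6, 0.8), letters[1:3])
  h <- wpgma(d3)
  expect_error(cut_groups(h, 0), "between")
  expect_error(cut_groups(h, 4), "between")
  expect_equal(unname(cut_groups(h, 1)), rep(1, 3))   # k = 1: one group
  expect_equal(length(unique(cut_groups(h, 3))), 3)   # k = n: singletons
})

test_that("cut_groups partitions are hierarchically nested", {
  set.seed(22)
  n <- 12
  D <- dist_matrix(runif(n * (n - 1) / 2), sprintf("l%02d", 1:n))
  h <- wpgma(D)
  for (k in 2:n) {
    fine <- cut_groups(h, k)
    coarse <- cut_groups(h, k - 1)
    # every fine group lies within exactly one coarse group
    expect_true(all(tapply(coarse, fine, function(x) length(unique(x))) == 1))
  }
})

test_that("consolidation keeps major groups and reassigns minor ones", {
  # two tight clusters plus two stragglers, planted in a distance matrix
  labels <- sprintf("c%02d", 1:10)
  D <- matrix(0.9, 10, 10, dimnames = list(labels, labels))
  D[1:4, 1:4] <- 0.05; D[5:8, 5:8] <- 0.05
  D[9, 1:4] <- D[1:4, 9] <- 0.2   # straggler near cluster 1
  D[10, 5:8] <- D[5:8, 10] <- 0.2 # straggler near cluster 2
  diag(D) <- 0
  h <- wpgma(D)
  grp <- cut_groups(h, 4)
  a <- consolidate_districts(grp, h, k_final = 2)
  expect_equal(sort(unique(a$district)), c("D1", "D2"))
  expect_equal(nrow(a), 10)
  d_of <- setNames(a$district, a$cell_id)
  expect_equal(unname(d_of["c09"]), unname(d_of["c01"]))
  expect_equal(unname(d_of["c10"]), unname(d_of["c05"]))
  expect_error(consolidate_districts(grp, h, k_final = 5), "groups")
})

test_that("consolidation is the identity when no minor groups exist", {
  d3 <- dist_matrix(c(0.1, 0.8, 0.8, 0.8, 0.8, 0.1), letters[1:4])
  h <- wpgma(d3)
  grp <- cut_groups(h, 2)
  a <- consolidate_districts(grp, h, k_final = 2)
  expect_true(all(a$provenance == "cluster"))
  expect_equal(length(unique(paste(grp, a$district))), 2)  # same partition
})

test_that("mrpp detects perfect separation with the smallest possible p", {
  # groups large enough that a random permutation essentially never
  # recreates the planted split, so no permuted delta ties the observed 0
  labels <- sprintf("c%02d", 1:16)
  D <- matrix(1, 16, 16, dimnames = list(labels, labels))
  D[1:8, 1:8] <- 0; D[9:16, 9:16] <- 0; diag(D) <- 0
  g <- setNames(rep(c("u", "v"), each = 8), labels)
  m <- mrpp_test(D, g, permutations = 99, seed = 1)
  expect_equal(m$observed_delta, 0)
  expect_equal(m$p_value, 1 / 100)
  expect_gt(m$A, 0)
})

test_that("mrpp delta matches hand arithmetic and exhaustive enumeration", {
  labels <- sprintf("p%d", 1:6)
  set.seed(23)
  D <- dist_matrix(runif(15), labels)
  g <- setNames(rep(c("g1", "g2"), each = 3), labels)
  m <- mrpp_test(D, g, permutations = 9999, seed = 2)
  # hand arithmetic: mean of the three within-pair distances per group
  xi1 <- mean(D[cbind(c(1, 1, 2), c(2, 3, 3))])
  xi2 <- mean(D[cbind(c(4, 4, 5), c(5, 6, 6))])
  expect_equal(m$observed_delta, 0.5 * xi1 + 0.5 * xi2, tolerance = 1e-12)
  # exhaustive null: all 20 ways to choose group 1
  splits <- combn(6, 3)
  delta_all <- apply(splits, 2, function(i) {
    x1 <- mean(D[i, i][lower.tri(diag(3))])
    x2 <- mean(D[-i, -i][lower.tri(diag(3))])
    0.5 * x1 + 0.5 * x2
  })
  p_exact <- mean(delta_all <= m$observed_delta)
  expect_lt(abs(m$p_value - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 9999) + 1e-4)
  # A is positive exactly when observed delta is below the permutation mean
  expect_equal(m$A > 0, m$observed_delta < mean(m$delta_perm))
})

test_that("mrpp is invariant to group label names and validates input", {
  labels <- sprintf("p%d", 1:8)
  set.seed(24)
  D <- dist_matrix(runif(28), labels)
  g1 <- setNames(rep(c("x", "y"), 4), labels)
  g2 <- setNames(rep(c("north", "south"), 4), labels)
  m1 <- mrpp_test(D, g1, permutations = 199, seed = 5)
  m2 <- mrpp_test(D, g2, permutations = 199, seed = 5)
  expect_equal(m1$observed_delta, m2$observed_delta)
  expect_equal(m1$p_value, m2$p_value)
  expect_error(mrpp_test(D, setNames(rep("one", 8), labels)), "2 groups")
  expect_error(mrpp_test(D, setNames(c("a", rep("b", 7)), labels)), ">= 2 members")
})

test_that("mrpp agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  labels <- sprintf("p%d", 1:10)
  set.seed(25)
  D <- dist_matrix(runif(45), labels)
  g <- setNames(rep(c("a", "b"), 5), labels)
  ours <- mrpp_test(D, g, permutations = 999, seed = 1)
  ref <- vegan::mrpp(as.dist(D), g, permutations = 999, weight.type = 1)
  expect_equal(ours$observed_delta, ref$delta, tolerance = 1e-12)
  expect_equal(sort(ours$group_stats$xi), unname(sort(ref$classdelta)),
               tolerance = 1e-12)
  expect_lt(abs(ours$A - ref$A), 0.02)          # both estimate E(delta) by MC
  expect_lt(abs(ours$p_value - ref$Pvalue), 0.05)
})

test_that("regionalize recovers the planted districts", {
  skip_if_not_installed("mclust")
  fx <- planted_fixture(seed = 1)
  rg <- regionalize(fx$ct, k_groups = 8, k_final = 2, permutations = 99, seed = 1)
  truth <- setNames(fx$landscape$cells$district, fx$landscape$cells$cell_id)
  got <- districts(rg)
  ari <- mclust::adjustedRandIndex(got, truth[names(got)])
  expect_gt(ari, 0.9)
  expect_lt(rg$mrpp$p_value, 0.05)
  expect_equal(sum(table(rg$assignment$district)), nrow(fx$ct$cells))
})
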