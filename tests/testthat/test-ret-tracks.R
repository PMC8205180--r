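toy_scores <- function(n = 20, seed = 61) {
  set.seed(seed)
  sc <- matrix(rnorm(2 * n), n, 2,
               dimnames = list(sprintf("c%02d", 1:n), c("NMDS1", "NMDS2")))
  scale(sc, scale = FALSE)
}

test_that("a variable equal to axis-1 scores fits perfectly", {
  sc <- toy_scores()
  env <- data.frame(cell_id = rownames(sc), v = sc[, 1])
  fit <- env_vectors(sc, env, permutations = 999, seed = 1)
  expect_equal(fit$vectors$r2, 1, tolerance = 1e-10)
  expect_equal(abs(fit$vectors$NMDS1), 1, tolerance = 1e-8)
  expect_equal(fit$vectors$NMDS2, 0, tolerance = 1e-8)
  expect_equal(fit$vectors$p_value, 1 / 1000)
})

test_that("envfit validates input and directions are unit vectors", {
  sc <- toy_scores()
  expect_error(env_vectors(sc, data.frame(cell_id = rownames(sc), k = 1),
                           permutations = 9), "constant")
  set.seed(62)
  env <- data.frame(cell_id = rownames(sc), a = rnorm(20), b = rnorm(20))
  fit <- env_vectors(sc, env, permutations = 99, seed = 2)
  norms <- sqrt(fit$vectors$NMDS1^2 + fit$vectors$NMDS2^2)
  expect_equal(norms, rep(1, 2), tolerance = 1e-10)
  expect_true(all(fit$vectors$r2 >= 0 & fit$vectors$r2 <= 1))
  expect_true(all(fit$vectors$p_value > 0 & fit$vectors$p_value <= 1))
})

test_that("envfit r2 is invariant to rotation of the ordination axes", {
  sc <- toy_scores(seed = 63)
  set.seed(64)
  env <- data.frame(cell_id = rownames(sc), v = rnorm(20))
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  scR <- sc %*% R
  colnames(scR) <- colnames(sc)
  f1 <- env_vectors(sc, env, permutations = 99, seed = 5)
  f2 <- env_vectors(scR, env, permutations = 99, seed = 5)
  expect_equal(f1$vectors$r2, f2$vectors$r2, tolerance = 1e-10)
  # the fitted direction rotates with the axes
  d1 <- c(f1$vectors$NMDS1, f1$vectors$NMDS2)
  d2 <- c(f2$vectors$NMDS1, f2$vectors$NMDS2)
  expect_equal(abs(sum((d1 %*% R) * d2)), 1, tolerance = 1e-8)
})

test_that("envfit r2 matches an independent implementation", {
  skip_if_not_installed("vegan")
  sc <- toy_scores(seed = 65)
  set.seed(66)
  env <- data.frame(a = rnorm(20), b = rnorm(20), c = rnorm(20))
  fit <- env_vectors(sc, data.frame(cell_id = rownames(sc), env),
                     permutations = 99, seed = 3)
  ref <- vegan::envfit(sc, env, permutations = 0)
  expect_equal(fit$vectors$r2, unname(ref$vectors$r), tolerance = 1e-10)
})

test_that("exclusive species are exactly the single-district species", {
  sets <- list(c1 = c("only_here", "everywhere"), c2 = c("everywhere", "south1"),
               c3 = c("south1", "south2"))
  assign <- data.frame(cell_id = c("c1", "c2", "c3"),
                       district = c("N", "S", "S"),
                       provenance = "cluster")
  exc <- exclusive_species(sets, assign)
  expect_equal(exc$N, "only_here")
  expect_equal(exc$S, c("south1", "south2"))
  # partition property: no species in both lists
  expect_length(intersect(exc$N, exc$S), 0)
})

test_that("recovered exclusive lists respect the planted truth", {
  fx <- planted_fixture(seed = 2)
  truth <- setNames(fx$landscape$cells$district, fx$landscape$cells$cell_id)
  assign <- data.frame(cell_id = names(truth), district = unname(truth),
                       provenance = "cluster")
  exc <- exclusive_species(fx$ct, assign)
  # every sampled planted-exclusive species is recovered for its district
  sampled_a <- unique(fx$occ$species[startsWith(fx$occ$species, "exclA")])
  expect_true(all(sampled_a %in% exc$A))
  # a shared species recorded in both districts appears in neither list
  shared <- unique(fx$occ$species[startsWith(fx$occ$species, "shared")])
  rec_district <- truth[fx$occ$cell_id]
  both <- vapply(shared, function(s) {
    length(unique(rec_district[fx$occ$species == s])) == 2
  }, logical(1))
  expect_false(any(shared[both] %in% c(exc$A, exc$B)))
})

test_that("two points give a single haversine edge", {
  pts <- data.frame(lon = c(-100, -101), lat = c(17, 17))
  tr <- mst_track(pts)
  expect_equal(nrow(tr$edges), 1)
  ref <- geosphere::distHaversine(c(-100, 17), c(-101, 17)) / 1000
  expect_equal(tr$total_length_km, ref, tolerance = 1e-10)
})

test_that("three collinear equidistant points form a chain", {
  pts <- data.frame(lon = c(-100, -101, -102), lat = c(0, 0, 0))
  tr <- mst_track(pts)
  expect_equal(nrow(tr$edges), 2)
  # two short edges, never the long one
  expect_true(all(tr$edges$length_km < 1.5 * min(tr$edges$length_km)))
})

test_that("tracks validate input and collapse duplicate points", {
  expect_error(mst_track(data.frame(lon = 1, lat = 1)), "2 distinct")
  dup <- data.frame(lon = c(1, 1, 2), lat = c(1, 1, 1))
  tr <- mst_track(dup)
  expect_equal(nrow(tr$points), 2)
  expect_equal(nrow(tr$edges), 1)
})

test_that("the tree is spanning, acyclic and minimal against the oracle", {
  set.seed(67)
  for (rep in 1:10) {
    n <- 6
    pts <- data.frame(lon = runif(n, -103, -100), lat = runif(n, 16, 19))
    tr <- mst_track(pts)
    expect_equal(nrow(tr$edges), n - 1)
    # connectivity via union of edges
    g <- seq_len(n)
    for (e in seq_len(n - 1)) {
      a <- g[tr$edges$from[e]]; b <- g[tr$edges$to[e]]
      g[g == b] <- a
    }
    expect_equal(length(unique(g)), 1)
    # exhaustive minimality
    D <- geosphere::distm(as.matrix(tr$points), fun = geosphere::distHaversine) / 1000
    expect_equal(tr$total_length_km, oracle_mst_min_length(D), tolerance = 1e-9)
  }
})

test_that("mst never exceeds a hand-constructed spanning tree", {
  set.seed(68)
  pts <- data.frame(lon = runif(8, 0, 5), lat = runif(8, 0, 5))
  tr <- mst_track(pts)
  D <- geosphere::distm(as.matrix(tr$points), fun = geosphere::distHaversine) / 1000
  chain <- sum(D[cbind(1:7, 2:8)])   # path through points in order
  star <- sum(D[1, -1])              # star from the first point
  expect_lte(tr$total_length_km, chain + 1e-9)
  expect_lte(tr$total_length_km, star + 1e-9)
})

test_that("per-district tracks are built from exclusive-species records", {
  fx <- planted_fixture(seed = 8)
  truth <- setNames(fx$landscape$cells$district, fx$landscape$cells$cell_id)
  assign <- data.frame(cell_id = names(truth), district = unname(truth),
                       provenance = "cluster")
  exc <- exclusive_species(fx$ct, assign)
  trks <- biogeographic_tracks(fx$occ, exc)
  expect_setequal(names(trks), c("A", "B"))
  for (tr in trks) expect_equal(nrow(tr$edges), nrow(tr$points) - 1)
  # A has many more exclusive species, hence at least as many track points
  expect_gte(nrow(trks$A$points), nrow(trks$B$points))
})
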