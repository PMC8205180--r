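test_that("pixel aggregation averages pixel centres per cell", {
  g <- grid_spec(origin = c(0, 0), cell_size = 1)
  px <- data.frame(lon = c(0.1, 0.4, 0.6, 0.9), lat = rep(0.5, 4),
                   v = c(1, 2, 3, 4))
  out <- aggregate_pixels(px, g)
  expect_equal(out$v, 2.5)
  # constant field -> every cell equals the constant
  px2 <- data.frame(lon = runif(50, 0, 3), lat = runif(50, 0, 3), v = 7)
  out2 <- aggregate_pixels(px2, g)
  expect_true(all(out2$v == 7))
})

test_that("pixel aggregation equals a brute-force binning oracle", {
  set.seed(41)
  px <- data.frame(lon = runif(300, 0, 4), lat = runif(300, 0, 4),
                   a = rnorm(300), b = runif(300))
  g <- grid_spec(origin = c(0, 0), cell_size = 1)
  out <- aggregate_pixels(px, g)
  key <- sprintf("c%03d_%03d", floor(px$lon), floor(px$lat))
  for (v in c("a", "b")) {
    oracle <- tapply(px[[v]], key, mean)
    expect_equal(unname(out[[v]]), as.numeric(oracle[out$cell_id]),
                 tolerance = 1e-12)
  }
})

test_that("cells without pixel coverage are flagged and excluded", {
  px <- data.frame(lon = 0.5, lat = 0.5, v = 1)
  g <- grid_spec(origin = c(0, 0), cell_size = 1)
  expect_warning(out <- aggregate_pixels(px, g, cells = c("c000_000", "c005_005")),
                 "no pixel coverage")
  expect_equal(out$cell_id, "c000_000")
  expect_equal(attr(out, "missing_cells"), "c005_005")
})

test_that("collinearity pruning drops duplicates and constants", {
  set.seed(42)
  x <- rnorm(30)
  env <- data.frame(cell_id = sprintf("c%02d", 1:30),
                    v1 = x, v2 = x, v3 = rnorm(30), flat = 5)
  pr <- prune_collinear(env, threshold = 0.8)
  expect_true("flat" %in% pr$dropped$dropped)
  expect_equal(sum(pr$dropped$dropped %in% c("v1", "v2")), 1)
  expect_true("v3" %in% names(pr$env))
  expect_equal(pr$dropped$r[pr$dropped$reason == "collinear"], 1, tolerance = 1e-12)
  # below-threshold table is untouched
  env2 <- data.frame(cell_id = sprintf("c%02d", 1:30),
                     a = rnorm(30), b = rnorm(30))
  pr2 <- prune_collinear(env2, threshold = 0.8)
  expect_equal(nrow(pr2$dropped), 0)
  expect_equal(names(pr2$env), c("cell_id", "a", "b"))
})

test_that("greedy pruning follows the stated algorithm on a known structure", {
  set.seed(43)
  n <- 200
  z <- rnorm(n)
  # v1, v2, v3 mutually collinear (built from z); v4, v5 independent
  env <- data.frame(cell_id = sprintf("c%03d", 1:n),
                    v1 = z + rnorm(n, sd = 0.1),
                    v2 = z + rnorm(n, sd = 0.1),
                    v3 = z + rnorm(n, sd = 0.3),
                    v4 = rnorm(n), v5 = rnorm(n))
  pr <- prune_collinear(env, threshold = 0.8)
  # hand trace of the greedy rule on the same data
  m <- as.matrix(env[, -1])
  kept <- colnames(m)
  repeat {
    r <- abs(cor(m[, kept])); diag(r) <- 0
    if (max(r) <= 0.8) break
    worst <- which(r == max(r), arr.ind = TRUE)[1, ]
    pair <- kept[worst]
    mr <- colMeans(r)[pair]
    drop <- pair[which.max(mr)]
    kept <- setdiff(kept, drop)
  }
  expect_equal(setdiff(names(pr$env), "cell_id"), kept)
})

test_that("standardization is exact, idempotent and invertible", {
  env <- data.frame(cell_id = c("a", "b", "c"), x = c(1, 2, 3), y = c(10, 0, 20))
  z <- standardize_env(env)
  expect_equal(z$x, c(-1, 0, 1))
  z2 <- standardize_env(z[names(env)])
  expect_equal(z2$x, z$x, tolerance = 1e-10)
  expect_equal(z2$y, z$y, tolerance = 1e-10)
  back <- unstandardize_env(z)
  expect_equal(back$x, env$x, tolerance = 1e-10)
  expect_equal(back$y, env$y, tolerance = 1e-10)
  expect_error(standardize_env(data.frame(cell_id = c("a", "b"), k = c(1, 1))),
               "constant")
})

test_that("rda proportion explained matches the closed-form oracle", {
  set.seed(44)
  Y <- matrix(rnorm(200), 20, 10)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  fit <- rda_fit(Y, X)
  # direct least-squares oracle: tr(Yhat' Yhat) / tr(Y'Y) on centred matrices
  Yc <- scale(Y, scale = FALSE); Xc <- scale(X, scale = FALSE)
  B <- solve(t(Xc) %*% Xc, t(Xc) %*% Yc)
  Yhat <- Xc %*% B
  expect_equal(fit$proportion_explained, sum(Yhat^2) / sum(Yc^2),
               tolerance = 1e-10)
  # orthogonal predictors explain nothing; exact linear response everything
  Yorth <- qr.resid(qr(cbind(1, Xc)), matrix(rnorm(200), 20, 10))
  expect_equal(rda_fit(Yorth, X)$proportion_explained, 0, tolerance = 1e-10)
  Ylin <- Xc %*% matrix(rnorm(30), 3, 10)
  expect_equal(rda_fit(Ylin, X)$proportion_explained, 1, tolerance = 1e-10)
})

test_that("rda names linearly dependent predictor columns", {
  set.seed(45)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("p", "q")))
  X <- cbind(X, dup = X[, 1] + X[, 2])
  expect_error(rda_fit(matrix(rnorm(100), 20, 5), X), "dup")
})

test_that("rda agrees with an independent constrained-ordination fit", {
  skip_if_not_installed("vegan")
  set.seed(46)
  Y <- matrix(rnorm(300), 30, 10)
  X <- data.frame(a = rnorm(30), b = rnorm(30), c = rnorm(30))
  fit <- rda_fit(Y, as.matrix(X))
  ref <- vegan::rda(Y ~ a + b + c, data = X)
  ref_prop <- ref$CCA$tot.chi / ref$tot.chi
  expect_equal(fit$proportion_explained, ref_prop, tolerance = 1e-10)
})

test_that("rda proportion is invariant to rotation of the predictor space", {
  set.seed(47)
  Y <- matrix(rnorm(200), 20, 10)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  XR <- X %*% R
  colnames(XR) <- colnames(X)
  expect_equal(rda_fit(Y, XR)$proportion_explained,
               rda_fit(Y, X)$proportion_explained, tolerance = 1e-10)
})

test_that("a perfect predictor is admitted first with the smallest p", {
  set.seed(48)
  x <- rnorm(30)
  Y <- outer(x, rnorm(8))                      # Y generated entirely by x
  X <- cbind(signal = x, noise1 = rnorm(30), noise2 = rnorm(30))
  fs <- forward_select(Y, X, permutations = 99, alpha = 0.05, seed = 1)
  expect_equal(fs$steps$variable[1], "signal")
  expect_equal(fs$steps$p_value[1], 1 / 100)
})

test_that("AIC-only forward selection yields a monotone non-increasing path", {
  set.seed(49)
  n <- 40
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("v", 1:5)))
  B <- matrix(rnorm(5 * 12, sd = c(2, 1.5, 1, 0, 0)), 5, 12)
  Y <- X %*% B + matrix(rnorm(n * 12), n, 12)
  fs <- forward_select(Y, X, stop_rule = "aic", alpha = 1)
  expect_gt(nrow(fs$steps), 1)
  expect_true(all(diff(fs$steps$AIC) <= 0))
  # every admitted step improves on the AIC of the model before it
  aic_empty <- n * log(sum(scale(Y, scale = FALSE)^2) / n) + 2
  expect_lt(fs$steps$AIC[1], aic_empty)
})

test_that("permutation p-values live on the discrete permutation grid", {
  set.seed(50)
  Y <- matrix(rnorm(25 * 6), 25, 6)
  X <- cbind(a = rnorm(25), b = rnorm(25))
  fs <- forward_select(Y, X, permutations = 19, alpha = 1, seed = 2)
  ok <- fs$steps$p_value %in% ((1:20) / 20)
  expect_true(all(ok))
})

test_that("pure-noise predictors are mostly rejected", {
  set.seed(51)
  admitted <- vapply(1:25, function(i) {
    Y <- matrix(rnorm(25 * 8), 25, 8)
    X <- matrix(rnorm(25 * 4), 25, 4, dimnames = list(NULL, paste0("n", 1:4)))
    fs <- suppressWarnings(forward_select(Y, X, permutations = 59,
                                          alpha = 0.05, seed = i))
    nrow(fs$steps) > 0
  }, logical(1))
  expect_lt(mean(admitted), 0.3)   # full calibration is exercised elsewhere
})
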