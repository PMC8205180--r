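# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG so library code never perturbs user-level reproducibility.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Ray-casting point-in-polygon with closed-boundary convention: points on an
# edge or vertex count as inside.  `poly` is a two-column matrix of vertices
# (closed or open ring).  Returns a logical vector.
point_in_polygon <- function(x, y, poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) >= 2L &&
      isTRUE(all(poly[1L, ] == poly[nrow(poly), ]))) {
    poly <- poly[-nrow(poly), , drop = FALSE]
  }
  nv <- nrow(poly)
  if (nv < 3L) stop("polygon needs at least 3 vertices", call. = FALSE)
  n <- length(x)
  inside <- logical(n)
  on_edge <- logical(n)
  px <- poly[, 1L]; py <- poly[, 2L]
  j <- nv
  for (i in seq_len(nv)) {
    x1 <- px[j]; y1 <- py[j]; x2 <- px[i]; y2 <- py[i]
    # boundary test: point collinear with and within the segment's bbox
    cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
    on_seg <- abs(cross) < 1e-12 &
      x >= pmin(x1, x2) - 1e-12 & x <= pmax(x1, x2) + 1e-12 &
      y >= pmin(y1, y2) - 1e-12 & y <= pmax(y1, y2) + 1e-12
    on_edge <- on_edge | on_seg
    crosses <- ((y1 > y) != (y2 > y)) &
      (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside | on_edge
}

stopifnot_scalar_number <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower) {
    stop(sprintf("'%s' must be a single number >= %s", name, lower),
         call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
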