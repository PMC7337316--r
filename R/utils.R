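# Internal helpers shared across modules. Coordinates are 1-based (row, col),
# rows increase downward. Homographies act on homogeneous (x = col, y = row).

assert_scalar_num <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]", name,
                  format(min), format(max)))
  }
  invisible(x)
}

is_binary_mask <- function(x) {
  is.matrix(x) && all(x %in% c(0L, 1L, 0, 1))
}

assert_mask <- function(mask, name = "mask") {
  if (!is_binary_mask(mask)) abort(sprintf("`%s` must be a 0/1 matrix", name))
  invisible(mask)
}

#' Apply a homography to points
#'
#' @param h 3x3 projective matrix acting on homogeneous `(x = col, y = row)`.
#' @param pts n x 2 matrix of `(row, col)` points.
#' @return n x 2 matrix of transformed `(row, col)` points.
#' @keywords internal
#' @noRd
homography_apply <- function(h, pts) {
  pts <- rbind_points(pts)
  p <- h %*% rbind(pts[, 2L], pts[, 1L], 1)
  cbind(row = p[2L, ] / p[3L, ], col = p[1L, ] / p[3L, ])
}

rbind_points <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2L, byrow = FALSE,
                                       dimnames = list(NULL, c("row", "col")))
  pts
}

# Shoelace area of a closed polygon given as n x 2 (row, col); absolute value.
polygon_area <- function(poly) {
  x <- poly[, 2L]; y <- poly[, 1L]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Scanline rasterization: pixels whose 1-based centers fall inside the closed
# polygon (n x 2, (row, col), not necessarily closed explicitly).
rasterize_polygon <- function(poly, nrow_out, ncol_out) {
  mask <- matrix(0L, nrow_out, ncol_out)
  yr <- poly[, 1L]; xc <- poly[, 2L]
  n <- length(yr)
  nxt <- c(seq_len(n)[-1L], 1L)
  r_min <- max(1L, floor(min(yr)))
  r_max <- min(nrow_out, ceiling(max(yr)))
  if (r_min > r_max) return(mask)
  y1 <- yr; y2 <- yr[nxt]; x1 <- xc; x2 <- xc[nxt]
  keep <- y1 != y2                       # horizontal edges contribute nothing
  y1 <- y1[keep]; y2 <- y2[keep]; x1 <- x1[keep]; x2 <- x2[keep]
  for (r in r_min:r_max) {
    # even-odd rule with half-open edge intervals to avoid double counting
    cross <- (y1 <= r & y2 > r) | (y2 <= r & y1 > r)
    if (!any(cross)) next
    xs <- x1[cross] + (r - y1[cross]) * (x2[cross] - x1[cross]) /
      (y2[cross] - y1[cross])
    xs <- sort(xs)
    for (k in seq(1L, length(xs) - 1L, by = 2L)) {
      c0 <- ceiling(xs[k] - 1e-9); c1 <- floor(xs[k + 1L] + 1e-9)
      c0 <- max(1L, c0); c1 <- min(ncol_out, c1)
      if (c0 <= c1) mask[r, c0:c1] <- 1L
    }
  }
  mask
}

# Jaccard overlap of two 0/1 masks of equal dimension.
mask_jaccard <- function(a, b) {
  inter <- sum(a == 1L & b == 1L)
  uni <- sum(a == 1L | b == 1L)
  if (uni == 0L) return(1)
  inter / uni
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Run `expr` with a private RNG stream so callers' .Random.seed is untouched.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}
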