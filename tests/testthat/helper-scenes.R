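# Shared fixtures, built in code and cached across test files so expensive
# renders and pipeline runs happen once per session.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# A mid-size leaf with a notched apex and acute base, rendered frontally.
std_shape <- function() {
  leaf_shape(10, 8, "concave", "convex", notch_depth_cm = 1, seed = 3)
}

std_render <- function() {
  cached("std_render",
         render_scene(leaf_scene(std_shape(), px_per_cm = 20, noise_sd = 0,
                                 seed = 5)))
}

# Fully convex counterpart.
convex_render <- function() {
  cached("convex_render",
         render_scene(leaf_scene(leaf_shape(10, 8, seed = 2),
                                 px_per_cm = 20, noise_sd = 0, seed = 7)))
}

# Mixed-morphology scene suite through the full pipeline (moderate size to
# keep the default test run fast); returns list of (render, run) pairs.
pipeline_suite <- function() {
  cached("pipeline_suite", {
    scenes <- random_scenes(10, seed = 202)
    lapply(scenes, function(sc) {
      rnd <- render_scene(sc)
      list(render = rnd,
           run = measure_image(rnd$image,
                               leaf_config(keep_intermediates = TRUE)))
    })
  })
}

# Second-moments principal axis of a mask, degrees from vertical, signed
# like the tilt convention (positive = top leans right). Independent of the
# package's midline-fit skew estimator.
principal_axis_deg <- function(mask) {
  idx <- which(mask == 1L)
  r <- (idx - 1L) %% nrow(mask) + 1L
  c <- (idx - 1L) %/% nrow(mask) + 1L
  r <- r - mean(r); c <- c - mean(c)
  ang <- 0.5 * atan2(2 * mean(r * c), mean(c^2) - mean(r^2)) * 180 / pi
  # ang is the major axis from horizontal in (col, row-down) coords
  from_vertical <- 90 + ang
  if (from_vertical > 90) from_vertical <- from_vertical - 180
  from_vertical
}

jaccard <- function(a, b) {
  sum(a == 1L & b == 1L) / sum(a == 1L | b == 1L)
}

# A random viewing-angle warp for a 580 x 420 px sheet: area-preserving
# (camera inclination, not zoom) and generic (every image edge tilted at
# least ~0.35 degrees from the pixel axes, as for any real hand-held pose;
# an edge aligned to within one staircase step carries almost no sub-pixel
# slope information). Returns 4 x 2 corner displacements (TL, TR, BR, BL).
generic_sheet_warp <- function(mag = 10, min_tilt = 0.0061) {
  ideal <- cbind(c(0, 0, 580, 580), c(0, 420, 420, 0))
  repeat {
    quad <- ideal + matrix(runif(8, -mag, mag), 4, 2)
    a0 <- leafmetrics:::polygon_area(ideal)
    a1 <- leafmetrics:::polygon_area(quad)
    ctr <- colMeans(quad)
    quad <- sweep(sweep(quad, 2, ctr), 1:2, sqrt(a0 / a1), "*") +
      rep(1, 4) %o% ctr
    sides <- rbind(quad[2, ] - quad[1, ], quad[3, ] - quad[2, ],
                   quad[4, ] - quad[3, ], quad[1, ] - quad[4, ])
    tilt <- c(abs(sides[1, 1] / sides[1, 2]), abs(sides[2, 2] / sides[2, 1]),
              abs(sides[3, 1] / sides[3, 2]), abs(sides[4, 2] / sides[4, 1]))
    if (all(tilt >= min_tilt)) return(quad - ideal)
  }
}

# Exhaustive concave-landmark search over the extremity decile, independent
# of boundary tracing and segment selection: boundary pixels (4-neighbour
# definition) within the band, horizontally interior to the flanking lobes
# (whose columns bound the extremum row's span), maximum vertical offset,
# ties to the pixel nearest the band's horizontal midpoint.
brute_concave <- function(mask, band, decile = 0.1) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(0L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  interior <- pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  idx <- which(mask == 1L & !interior)
  rr <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  rows_fg <- range(rr)
  depth <- max(2L, floor(decile * (rows_fg[2] - rows_fg[1] + 1L)))
  if (band == "top") {
    ref <- rows_fg[1]
    sel <- rr <= ref + depth
    off <- rr - ref
  } else {
    ref <- rows_fg[2]
    sel <- rr >= ref - depth
    off <- ref - rr
  }
  ext_cols <- cc[rr == ref]
  inner <- cc > min(ext_cols) & cc < max(ext_cols)
  cand <- which(sel & inner)
  cand <- cand[off[cand] == max(off[cand])]
  mid <- (min(cc[sel]) + max(cc[sel])) / 2
  cand <- cand[which.min(abs(cc[cand] - mid))]
  c(rr[cand], cc[cand])
}
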