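# Boundary tracing and tip / petiole-insertion localization.
#
# A convex extremity's landmark is simply the boundary's global vertical
# extremum. A concave (notched) extremity hides its landmark inside the
# notch: the global extremum sits on a flanking lobe instead. The concave
# path therefore selects a short boundary segment spanning both lobes,
# builds the curve of vertical offsets from the band's extremum row, and
# takes the peak of that curve -- the deepest point of the notch.

#' Trace the boundary of a single-component mask
#'
#' Moore-neighbour tracing with Jacob's stopping criterion, yielding the
#' closed 8-connected boundary. Orientation is normalized (interior to the
#' left walking the returned order) so arc positions are reproducible.
#'
#' @param mask 0/1 matrix with exactly one foreground component (use
#'   [keep_largest_component()] first).
#' @return An `edge_trace`: n x 2 integer matrix of `(row, col)` boundary
#'   pixels in cyclic order.
#' @export
trace_boundary <- function(mask) {
  assert_mask(mask)
  idx <- which(mask == 1L)
  if (!length(idx)) abort("mask has no foreground pixels")
  nr <- nrow(mask); nc <- ncol(mask)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  r0 <- min(rr)
  c0 <- min(cc[rr == r0])                  # topmost, then leftmost
  # clockwise ring of 8 neighbours starting west
  ring <- cbind(c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L),
                c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L))
  fg <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc &&
    mask[r, c] == 1L
  cur <- c(r0, c0)
  back <- c(r0, c0 - 1L)                   # entered from the west
  cap <- 8L * length(idx) + 64L
  pts <- matrix(0L, cap, 2L)
  pts[1L, ] <- cur
  np <- 1L
  start <- cur; start_back <- back
  # cycle detection on the (pixel, backtrack-direction) state: Jacob's
  # criterion alone can fail on diagonally pinched masks
  seen <- new.env(hash = TRUE, parent = emptyenv())
  cycle_from <- 0L
  repeat {
    db <- back - cur
    k0 <- which(ring[, 1L] == db[1L] & ring[, 2L] == db[2L])
    key <- as.character(((cur[2L] - 1L) * nr + cur[1L] - 1L) * 8L + k0)
    if (!is.null(prev <- seen[[key]])) { cycle_from <- prev; break }
    seen[[key]] <- np
    found <- FALSE
    for (s in 1:8) {
      k <- ((k0 - 1L + s) %% 8L) + 1L
      cand <- cur + ring[k, ]
      if (fg(cand[1L], cand[2L])) {
        prev_k <- ((k0 - 1L + s - 1L) %% 8L) + 1L
        back <- cur + ring[prev_k, ]
        cur <- cand
        found <- TRUE
        break
      }
    }
    if (!found) break                      # isolated pixel
    if (all(cur == start) && all(back == start_back)) break
    np <- np + 1L
    pts[np, ] <- cur
  }
  out <- if (cycle_from > 1L) pts[cycle_from:np, , drop = FALSE]
  else pts[seq_len(np), , drop = FALSE]
  np <- nrow(out)
  # drop duplicate visits of the start produced by spur re-entry
  if (np > 1L && all(out[np, ] == out[1L, ])) out <- out[-np, , drop = FALSE]
  colnames(out) <- c("row", "col")
  class(out) <- c("edge_trace", class(out))
  out
}

trace_span <- function(trace) {
  list(min_row = min(trace[, 1L]), max_row = max(trace[, 1L]),
       min_col = min(trace[, 2L]), max_col = max(trace[, 2L]))
}

# Rows belonging to the top or bottom decile band of the leaf's row span.
band_limit <- function(trace, band, decile) {
  sp <- trace_span(trace)
  depth <- max(2L, floor(decile * (sp$max_row - sp$min_row + 1L)))
  if (band == "top") sp$min_row + depth else sp$max_row - depth
}

#' Select the boundary segment spanning an extremity
#'
#' One endpoint is the band's global vertical extremum (topmost pixel for
#' the top band, ties to the smallest column). For a notched extremity the
#' silhouette near the extremum is flat, so the most frequent (modal) row
#' among boundary pixels in the extremity's decile band identifies the
#' shoulder level; the second endpoint is the outermost pixel at that row
#' on the opposite side of the lamina's vertical midline. The segment is
#' the shorter boundary arc joining the endpoints.
#'
#' @param trace An `edge_trace`.
#' @param band `"top"` or `"bottom"`.
#' @param decile Band depth as a fraction of the leaf's row span.
#' @return An `edge_segment`: list with `points` (m x 2 arc in order),
#'   `endpoint_a`, `endpoint_b`, `band`.
#' @export
select_band_segment <- function(trace, band = c("top", "bottom"),
                                decile = 0.1) {
  band <- match.arg(band)
  rows <- trace[, 1L]; cols <- trace[, 2L]
  n <- nrow(trace)
  sp <- trace_span(trace)
  midline <- (sp$min_col + sp$max_col) / 2
  if (band == "top") {
    ext <- which(rows == sp$min_row)
    lim <- band_limit(trace, "top", decile)
    in_band <- rows <= lim
  } else {
    ext <- which(rows == sp$max_row)
    lim <- band_limit(trace, "bottom", decile)
    in_band <- rows >= lim
  }
  # extremum ties: take the outermost pixel (the leaf's top-left or
  # top-right point), so a notch adjacent to the extremum run stays
  # interior to the segment; remaining ties to the smaller column
  i_a <- ext[order(-abs(cols[ext] - midline), cols[ext])][1L]
  tab <- table(rows[in_band])
  modal_row <- as.integer(names(tab)[tab == max(tab)])
  modal_row <- if (band == "top") min(modal_row) else max(modal_row)
  on_right <- cols[i_a] <= midline
  cand <- which(rows == modal_row &
                  (if (on_right) cols > midline else cols < midline))
  if (!length(cand))
    cand <- setdiff(which(rows == modal_row), i_a)
  if (!length(cand)) cand <- i_a
  i_b <- cand[which.max(abs(cols[cand] - midline))]
  fwd_len <- (i_b - i_a) %% n + 1L
  bwd_len <- (i_a - i_b) %% n + 1L
  idx <- if (fwd_len <= bwd_len) {
    (seq.int(i_a - 1L, length.out = fwd_len) %% n) + 1L
  } else {
    (seq.int(i_a - 1L, by = -1L, length.out = bwd_len) %% n) + 1L
  }
  if (length(idx) > n / 2 + 1L)
    abort("extremity segment spans more than half the boundary",
          class = "leafmetrics_bad_segment")
  structure(list(points = trace[idx, , drop = FALSE],
                 endpoint_a = trace[i_a, ], endpoint_b = trace[i_b, ],
                 band = band),
            class = "edge_segment")
}

#' Vertical-offset difference curve along a segment
#'
#' Offsets of each segment pixel's row from the boundary's extremum row
#' (minimum row for the top band, maximum for the bottom), the quantity
#' whose peak marks a concave landmark.
#'
#' @param segment An `edge_segment`.
#' @param trace The parent `edge_trace` (supplies the extremum row).
#' @return A `difference_curve`: list with nonnegative integer `offsets`
#'   (one per segment pixel) and `reference_row`.
#' @export
difference_curve <- function(segment, trace) {
  stopifnot(inherits(segment, "edge_segment"))
  sp <- trace_span(trace)
  ref <- if (segment$band == "top") sp$min_row else sp$max_row
  off <- if (segment$band == "top") segment$points[, 1L] - ref
  else ref - segment$points[, 1L]
  structure(list(offsets = as.integer(off), reference_row = ref),
            class = "difference_curve")
}

#' Locate a concave landmark at the difference-curve peak
#'
#' @param curve A [difference_curve()].
#' @param segment The `edge_segment` the curve was built from.
#' @return `(row, col)` of the segment pixel at the curve's global maximum;
#'   ties resolve to the pixel nearest the segment's horizontal midpoint.
#' @export
locate_concave_point <- function(curve, segment) {
  off <- curve$offsets
  at <- which(off == max(off))
  if (length(at) > 1L) {
    mid <- (min(segment$points[, 2L]) + max(segment$points[, 2L])) / 2
    at <- at[which.min(abs(segment$points[at, 2L] - mid))]
  }
  segment$points[at[1L], ]
}

#' Locate convex landmarks at the boundary's global vertical extrema
#'
#' @param trace An `edge_trace`.
#' @return List with `tip` (minimum-row pixel) and `insertion` (maximum-row
#'   pixel); row ties resolve to the column nearest the boundary's column
#'   centroid.
#' @export
locate_convex_points <- function(trace) {
  rows <- trace[, 1L]; cols <- trace[, 2L]
  ctr <- mean(cols)
  pick <- function(at) {
    at <- at[order(abs(cols[at] - ctr), cols[at])][1L]
    trace[at, ]
  }
  list(tip = pick(which(rows == min(rows))),
       insertion = pick(which(rows == max(rows))))
}

# Shared concave-path analysis of one extremity.
extremity_analysis <- function(trace, band, decile = 0.1,
                               depth_threshold_px = 3L,
                               interior_frac = 0.2) {
  seg <- select_band_segment(trace, band, decile)
  cur <- difference_curve(seg, trace)
  p <- locate_concave_point(cur, seg)
  off <- if (band == "top") p[1L] - cur$reference_row
  else cur$reference_row - p[1L]
  # notch depth is measured below the flanking lobes (the segment
  # endpoints), not the global extremum, so boundary staircase jitter on a
  # smooth convex extremity cannot fake a notch
  end_off <- max(cur$offsets[1L], cur$offsets[length(cur$offsets)])
  depth <- off - end_off
  span <- abs(seg$endpoint_b[2L] - seg$endpoint_a[2L])
  d_end <- min(abs(p[2L] - seg$endpoint_a[2L]), abs(p[2L] - seg$endpoint_b[2L]))
  concave <- depth >= depth_threshold_px && span > 0 &&
    d_end >= interior_frac * span
  list(segment = seg, curve = cur, point = p, offset = off, depth = depth,
       concave = concave,
       near_threshold = abs(depth - depth_threshold_px) <= 1L)
}

#' Classify an extremity as concave or convex
#'
#' An extremity is concave when the provisional difference-curve landmark
#' is vertically offset from the band's extremum row by at least
#' `depth_threshold_px` AND lies horizontally interior to the two flanking
#' lobes (away from both segment endpoints); otherwise convex.
#'
#' @param trace An `edge_trace`.
#' @param band `"top"` or `"bottom"`.
#' @param depth_threshold_px Minimum notch depth in pixels.
#' @param decile Extremity band depth (fraction of the leaf's row span).
#' @return `"concave"` or `"convex"`.
#' @export
classify_extremity <- function(trace, band = c("top", "bottom"),
                               depth_threshold_px = 3L, decile = 0.1) {
  band <- match.arg(band)
  an <- extremity_analysis(trace, band, decile, depth_threshold_px)
  if (an$concave) "concave" else "convex"
}

#' Locate the leaf tip and petiole insertion
#'
#' Dispatches each extremity independently: the concave difference-curve
#' path when the extremity is classified concave, the global-extremum path
#' otherwise.
#'
#' @param mask De-skewed, cleaned 0/1 leaf mask.
#' @param decile Extremity band depth.
#' @param depth_threshold_px Concave/convex dispatch threshold (pixels).
#' @return A `leaf_landmarks`: list with `tip`, `insertion` (named `(row,
#'   col)` vectors), `tip_shape`, `base_shape`. `tidy()` gives a one-row
#'   tibble.
#' @export
find_landmarks <- function(mask, decile = 0.1, depth_threshold_px = 3L) {
  trace <- trace_boundary(mask)
  top <- extremity_analysis(trace, "top", decile, depth_threshold_px)
  bot <- extremity_analysis(trace, "bottom", decile, depth_threshold_px)
  cvx <- locate_convex_points(trace)
  tip <- if (top$concave) top$point else cvx$tip
  ins <- if (bot$concave) bot$point else cvx$insertion
  if (tip[1L] >= ins[1L])
    abort("tip does not lie above insertion; mask is not de-skewed?")
  structure(list(tip = c(row = unname(tip[1L]), col = unname(tip[2L])),
                 insertion = c(row = unname(ins[1L]),
                               col = unname(ins[2L])),
                 tip_shape = if (top$concave) "concave" else "convex",
                 base_shape = if (bot$concave) "concave" else "convex",
                 near_threshold = top$near_threshold || bot$near_threshold),
            class = "leaf_landmarks")
}

#' @export
tidy.leaf_landmarks <- function(x, ...) {
  tibble(tip_row = x$tip["row"], tip_col = x$tip["col"],
         insertion_row = x$insertion["row"],
         insertion_col = x$insertion["col"],
         tip_shape = x$tip_shape, base_shape = x$base_shape)
}
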