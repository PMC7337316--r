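# Perspective rectification from the reference sheet, foreground cleaning,
# and basal-midrib skew correction.
#
# Homographies are 3x3 matrices acting on homogeneous (x = col, y = row)
# coordinates, normalized so the bottom-right entry is 1. Rectification is
# an exact four-point direct linear solve: the sheet's detected corners map
# onto the corners of the target rectangle with zero residual.

# Exact 4-point DLT: solve the 8 unknowns mapping src[i,] -> dst[i,]
# ((row, col) points). Errors on (near-)collinear configurations.
dlt_homography <- function(src, dst) {
  src <- rbind_points(src); dst <- rbind_points(dst)
  stopifnot(nrow(src) == 4L, nrow(dst) == 4L)
  x <- src[, 2L]; y <- src[, 1L]; u <- dst[, 2L]; v <- dst[, 1L]
  a <- matrix(0, 8L, 8L)
  b <- numeric(8L)
  for (i in 1:4) {
    a[2L * i - 1L, ] <- c(x[i], y[i], 1, 0, 0, 0, -u[i] * x[i], -u[i] * y[i])
    a[2L * i, ]      <- c(0, 0, 0, x[i], y[i], 1, -v[i] * x[i], -v[i] * y[i])
    b[2L * i - 1L] <- u[i]
    b[2L * i] <- v[i]
  }
  h <- tryCatch(solve(a, b),
                error = function(e) abort(
                  "degenerate corner configuration (collinear corners?)"))
  matrix(c(h, 1), 3L, 3L, byrow = TRUE)
}

#' Detect the white sheet's four corners
#'
#' Takes a binary mask of bright (sheet) pixels, keeps the largest connected
#' component, and fits a quadrilateral: convex-hull points are searched for
#' the area-maximizing quadrilateral, then each side is refined sub-pixel
#' by fitting a line to the component's outermost boundary pixels under the
#' staircase constraint that the true edge passes within one pixel outward
#' of every boundary pixel centre, and adjacent sides are intersected.
#' Corners are therefore sub-pixel positions at the sheet's area boundary.
#'
#' @param paper_mask 0/1 matrix, 1 = sheet pixel (e.g.
#'   `channel > valley_threshold(...)`).
#' @param min_coverage Minimum fraction of the frame the sheet must cover.
#' @return 4 x 2 matrix of `(row, col)` corners ordered TL, TR, BR, BL.
#' @export
detect_paper_quad <- function(paper_mask, min_coverage = 0.2) {
  assert_mask(paper_mask, "paper_mask")
  comp <- largest_component(paper_mask)
  if (is.null(comp) || sum(comp) < min_coverage * length(paper_mask))
    abort("no bright quadrilateral region found (sheet missing?)",
          class = "leafmetrics_no_sheet")
  bnd <- mask_boundary_points(comp)
  hull <- bnd[grDevices::chull(bnd[, 2L], bnd[, 1L]), , drop = FALSE]
  corners <- max_area_quad(hull)
  corners <- order_corners(corners)
  # two refinement passes: the second re-assigns boundary pixels using the
  # sub-pixel sides from the first, stabilizing pixels near the corners
  refine_quad(refine_quad(corners, bnd), bnd)
}

# Pixels of the component with at least one 4-neighbour outside it.
mask_boundary_points <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  nb <- pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  idx <- which(core == 1L & !nb)
  cbind(row = ((idx - 1L) %% nr) + 1L, col = ((idx - 1L) %/% nr) + 1L)
}

# Deterministic local search for the maximum-area quadrilateral over hull
# points, initialized at the four diagonal extremes.
max_area_quad <- function(hull) {
  r <- hull[, 1L]; c <- hull[, 2L]
  pick <- c(which.min(r + c), which.min(r - c), which.max(r + c),
            which.max(r - c))
  quad_area <- function(id) polygon_area(hull[id, , drop = FALSE])
  repeat {
    improved <- FALSE
    for (k in 1:4) {
      best <- pick
      for (j in seq_len(nrow(hull))) {
        trial <- pick; trial[k] <- j
        if (length(unique(trial)) == 4L && quad_area(trial) >
            quad_area(best) + 1e-9) best <- trial
      }
      if (!identical(best, pick)) { pick <- best; improved <- TRUE }
    }
    if (!improved) break
  }
  hull[pick, , drop = FALSE]
}

# Order corners TL, TR, BR, BL by angle about the centroid, starting from
# the corner with the smallest row+col.
order_corners <- function(corners) {
  ctr <- colMeans(corners)
  ang <- atan2(corners[, 1L] - ctr[1L], corners[, 2L] - ctr[2L])
  corners <- corners[order(ang), , drop = FALSE]   # clockwise in image coords
  start <- which.min(corners[, 1L] + corners[, 2L])
  corners[((seq_len(4L) + start - 2L) %% 4L) + 1L, , drop = FALSE]
}

# Sub-pixel corner refinement: assign boundary pixels to the nearest initial
# side, fit each side, and intersect adjacent sides. Because the mask edge
# is a hard staircase, the true edge passes within (0, 1] of every inside
# boundary pixel centre along the outward normal; the side line is fitted as
# the centre of the widest feasible "tube" satisfying those constraints
# (margin-maximizing over a fine slope grid), which recovers sub-pixel slope
# even when a near-axis-aligned edge shows a single staircase step.
refine_quad <- function(corners, bnd, corner_margin = 2) {
  ctr <- colMeans(corners)
  lines <- vector("list", 4L)
  for (k in 1:4) {
    p1 <- corners[k, ]; p2 <- corners[(k %% 4L) + 1L, ]
    d <- p2 - p1
    len <- sqrt(sum(d^2))
    u <- d / len
    nrm <- c(u[2L], -u[1L])
    if (sum((p1 + nrm - ctr)^2) < sum((p1 - nrm - ctr)^2)) nrm <- -nrm
    rel_r <- bnd[, 1L] - p1[1L]; rel_c <- bnd[, 2L] - p1[2L]
    t <- rel_r * u[1L] + rel_c * u[2L]
    s <- rel_r * nrm[1L] + rel_c * nrm[2L]      # signed outward offset
    sel <- which(abs(s) <= 2.5 & t >= corner_margin & t <= len - corner_margin)
    if (length(sel) < 8L) { lines[[k]] <- list(p = p1, u = u); next }
    # keep only the outermost pixel per scanline: pixels of the adjacent
    # side near a shared corner sit further inside and would contaminate
    # both the constraints and the fit
    scan <- if (abs(u[1L]) >= abs(u[2L])) bnd[sel, 1L] else bnd[sel, 2L]
    keep <- unlist(lapply(split(seq_along(sel), scan),
                          function(ii) ii[which.max(s[sel][ii])]),
                   use.names = FALSE)
    sel <- sel[keep]
    ti <- t[sel]; si <- s[sel]
    n <- length(ti)
    bs <- seq(-0.04, 0.04, length.out = 321L)
    off <- -outer(bs, ti) + rep(si, each = length(bs))       # s_i - b t_i
    lo <- apply(off, 1L, max)
    hi <- apply(off, 1L, min) + 1
    margin <- hi - lo
    if (max(margin) > 0.25) {
      # few staircase steps: the feasible tube is wide and its Chebyshev
      # centre is the minimax edge estimate
      best <- which.max(margin)
      a <- (lo[best] + hi[best]) / 2
    } else {
      # many steps: insets are dense, the tube degenerates, and the
      # least-squares midline (intercept clamped into the tube) is right
      r_mean <- mean(si) + 0.5 - bs * mean(ti)
      a_cl <- pmin(pmax(r_mean, lo + 1e-6), hi)
      sse <- sum((si + 0.5)^2) - 2 * bs * sum((si + 0.5) * ti) +
        bs^2 * sum(ti^2) - 2 * n * a_cl * r_mean + n * a_cl^2
      feasible <- margin > 0
      best <- if (any(feasible)) which(feasible)[which.min(sse[feasible])]
      else which.max(margin)
      a <- if (feasible[best]) a_cl[best] else (lo[best] + hi[best]) / 2
    }
    b <- bs[best]
    lines[[k]] <- list(p = p1 + a * nrm, u = (u + b * nrm) / sqrt(1 + b^2))
  }
  out <- matrix(0, 4L, 2L, dimnames = list(NULL, c("row", "col")))
  for (k in 1:4) {
    la <- lines[[((k - 2L) %% 4L) + 1L]]        # side ending at corner k
    lb <- lines[[k]]                            # side starting at corner k
    out[k, ] <- line_intersect(la, lb)
  }
  out
}

line_intersect <- function(la, lb) {
  a <- cbind(la$u, -lb$u)
  t <- solve(a, lb$p - la$p)
  la$p + t[1L] * la$u
}

#' Estimate the rectifying homography from the sheet's corners
#'
#' Exact four-point solve mapping the detected corners onto the corners of a
#' `target_h` x `target_w` pixel rectangle (area corners, so the sheet fills
#' the target frame exactly). The target aspect ratio should match the
#' sheet's physical aspect ratio.
#'
#' @param quad 4 x 2 corner matrix from [detect_paper_quad()], TL, TR, BR, BL.
#' @param target_w,target_h Target rectangle size in pixels.
#' @return List with `matrix` (3x3, bottom-right entry 1), `target_w`,
#'   `target_h`; class `leaf_homography`.
#' @export
estimate_homography <- function(quad, target_w, target_h) {
  quad <- rbind_points(quad)
  dst <- cbind(row = c(0.5, 0.5, target_h + 0.5, target_h + 0.5),
               col = c(0.5, target_w + 0.5, target_w + 0.5, 0.5))
  m <- dlt_homography(quad, dst)
  if (abs(det(m)) < 1e-12) abort("homography is singular")
  structure(list(matrix = m, target_w = as.integer(target_w),
                 target_h = as.integer(target_h)),
            class = "leaf_homography")
}

#' Warp a raster through a homography
#'
#' Inverse-mapping resampler: each output pixel centre is pulled back
#' through the inverse transform and sampled from the input. Binary masks
#' use nearest-neighbour sampling (preserving 0/1 values); grayscale and
#' RGB use bilinear. Samples falling outside the input are background (0).
#'
#' @param x Matrix (mask or grayscale) or H x W x 3 array.
#' @param h A `leaf_homography` or bare 3x3 matrix mapping input to output
#'   coordinates.
#' @param out_dim `c(rows, cols)` of the output; defaults to the
#'   homography's target rectangle.
#' @param method `"auto"` (nearest for 0/1 masks, bilinear otherwise),
#'   `"nearest"`, or `"bilinear"`.
#' @return Warped raster of dimension `out_dim`.
#' @export
warp_image <- function(x, h, out_dim = NULL,
                       method = c("auto", "nearest", "bilinear")) {
  method <- match.arg(method)
  if (inherits(h, "leaf_homography")) {
    if (is.null(out_dim)) out_dim <- c(h$target_h, h$target_w)
    m <- h$matrix
  } else m <- h
  if (is.null(out_dim)) out_dim <- dim(x)[1:2]
  if (method == "auto")
    method <- if (is.matrix(x) && is_binary_mask(x)) "nearest" else "bilinear"
  minv <- solve(m)
  nr <- out_dim[1L]; nc <- out_dim[2L]
  grid_r <- rep(seq_len(nr), times = nc)
  grid_c <- rep(seq_len(nc), each = nr)
  src <- homography_apply(minv, cbind(grid_r, grid_c))
  if (is.matrix(x)) {
    out <- matrix(sample_plane(x, src, method), nr, nc)
    if (is_binary_mask(x)) out <- matrix(as.integer(out), nr, nc)
    attr(out, "foreground") <- attr(x, "foreground")
    return(out)
  }
  out <- array(0, dim = c(nr, nc, dim(x)[3L]))
  for (ch in seq_len(dim(x)[3L]))
    out[, , ch] <- matrix(sample_plane(x[, , ch], src, method), nr, nc)
  if (is.integer(x)) out <- array(as.integer(round(out)), dim = dim(out))
  out
}

sample_plane <- function(plane, src, method) {
  nr <- nrow(plane); nc <- ncol(plane)
  r <- src[, 1L]; c <- src[, 2L]
  if (method == "nearest") {
    ri <- round(r); ci <- round(c)
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    val <- numeric(length(r))
    val[ok] <- plane[cbind(ri[ok], ci[ok])]
    return(val)
  }
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  val <- numeric(length(r))
  ok <- r0 >= 1 & r0 + 1 <= nr & c0 >= 1 & c0 + 1 <= nc
  if (any(ok)) {
    i00 <- cbind(r0[ok], c0[ok]); i01 <- cbind(r0[ok], c0[ok] + 1)
    i10 <- cbind(r0[ok] + 1, c0[ok]); i11 <- cbind(r0[ok] + 1, c0[ok] + 1)
    val[ok] <- plane[i00] * (1 - fr[ok]) * (1 - fc[ok]) +
      plane[i01] * (1 - fr[ok]) * fc[ok] +
      plane[i10] * fr[ok] * (1 - fc[ok]) +
      plane[i11] * fr[ok] * fc[ok]
  }
  # fall back to nearest on the one-pixel frame so edge pixels are usable
  edge <- !ok & round(r) >= 1 & round(r) <= nr & round(c) >= 1 &
    round(c) <= nc
  if (any(edge)) val[edge] <- plane[cbind(round(r[edge]), round(c[edge]))]
  val
}

#' Crop a rectified mask to the sheet rectangle
#'
#' @param mask 0/1 matrix in the rectified frame.
#' @param rect `c(row0, row1, col0, col1)` extent of the sheet; default the
#'   whole frame (the usual case after warping onto the target rectangle).
#' @return Cropped mask. Warns (class `leafmetrics_clipped_leaf`) if
#'   foreground touches the crop boundary.
#' @export
crop_to_paper <- function(mask, rect = NULL) {
  assert_mask(mask)
  if (is.null(rect)) rect <- c(1L, nrow(mask), 1L, ncol(mask))
  out <- mask[rect[1L]:rect[2L], rect[3L]:rect[4L], drop = FALSE]
  if (sum(out) > 0 &&
      (any(out[1L, ] == 1L) || any(out[nrow(out), ] == 1L) ||
       any(out[, 1L] == 1L) || any(out[, ncol(out)] == 1L)))
    warn("foreground touches the crop boundary; leaf may be clipped",
         class = "leafmetrics_clipped_leaf")
  attr(out, "foreground") <- attr(mask, "foreground")
  out
}

# Largest connected component of a mask, or NULL if empty.
largest_component <- function(mask) {
  if (sum(mask) == 0L) return(NULL)
  lab <- EBImage::bwlabel(mask)
  tab <- tabulate(lab[lab > 0])
  keep <- which.max(tab)
  out <- matrix(as.integer(lab == keep), nrow(mask), ncol(mask))
  out
}

#' Keep the leaf: retain only the largest foreground component
#'
#' After cropping to the sheet, the leaf is the dominant dark region;
#' speckle and any residual border pixels form small separate components
#' and are removed (the paper's background/foreground swap-and-clean step).
#'
#' @param mask 0/1 matrix with leaf as foreground.
#' @return Cleaned mask (foreground = leaf, one component).
#' @export
keep_largest_component <- function(mask) {
  assert_mask(mask)
  out <- largest_component(mask)
  if (is.null(out)) abort("mask has no foreground pixels")
  attr(out, "foreground") <- "leaf"
  out
}

#' Estimate leaf skew from the basal midrib
#'
#' The midvein of the lamina straightens as it approaches the insertion, so
#' within the basal band (the lowest `basal_fraction` of leaf rows) the
#' row-wise horizontal midpoints of the silhouette track the midrib. A
#' least-squares line through those midpoints gives the signed angle of the
#' midrib from vertical (positive = top of the midrib leans right).
#'
#' @param mask Cleaned 0/1 leaf mask.
#' @param basal_fraction Fraction of leaf rows forming the basal band.
#' @return List with `angle_deg` and `support_rows`; class `leaf_skew`.
#' @export
basal_skew <- function(mask, basal_fraction = 0.2) {
  assert_mask(mask)
  assert_scalar_num(basal_fraction, "basal_fraction", 0.01, 0.5)
  rows_fg <- which(rowSums(mask) > 0)
  if (!length(rows_fg)) abort("mask has no foreground pixels")
  n_band <- ceiling(basal_fraction * length(rows_fg))
  band <- utils::tail(rows_fg, n_band)
  if (length(band) < 10L)
    abort("basal band too thin (< 10 leaf rows) for a skew fit",
          class = "leafmetrics_thin_base")
  ext <- vapply(band, function(r) {
    cc <- which(mask[r, ] == 1L)
    c(min(cc), max(cc))
  }, numeric(2))
  mid <- (ext[1L, ] + ext[2L, ]) / 2
  span <- ext[2L, ] - ext[1L, ] + 1
  # drop degenerate rows (quantized tip / truncation corners) whose
  # midpoints carry no midrib information
  keep <- span >= max(3, 0.4 * median(span))
  band <- band[keep]; mid <- mid[keep]
  if (length(band) < 10L)
    abort("basal band too thin (< 10 usable leaf rows) for a skew fit",
          class = "leafmetrics_thin_base")
  fit <- stats::lm.fit(cbind(1, band), mid)
  slope <- fit$coefficients[2L]            # d(col)/d(row)
  angle <- -atan(slope) * 180 / pi         # positive: top leans right
  if (!is.finite(angle) || abs(angle) > 45)
    abort("estimated skew exceeds 45 degrees; scene rejected")
  structure(list(angle_deg = unname(angle), support_rows = length(band)),
            class = "leaf_skew")
}

#' De-skew a leaf mask to a vertical midrib
#'
#' Repeats estimate-and-rotate until the basal skew estimate converges
#' (each pass estimates on the current pose but resamples the original
#' mask once, by the accumulated angle, so repeated rotation does not
#' erode the silhouette). At the fixed point the basal silhouette is
#' symmetric about the vertical, which removes the small tangent-averaging
#' bias a single midpoint fit carries at large tilts.
#'
#' @param mask Cleaned 0/1 leaf mask.
#' @param basal_fraction Passed to [basal_skew()].
#' @param tol Convergence tolerance in degrees.
#' @param max_iter Maximum estimate-rotate passes.
#' @return List with `mask` (de-skewed), `angle_deg` (total applied),
#'   `iterations`.
#' @export
deskew_mask <- function(mask, basal_fraction = 0.2, tol = 0.2,
                        max_iter = 10L) {
  total <- 0
  out <- mask
  best <- list(total = 0, est = Inf, mask = mask)
  for (i in seq_len(max_iter)) {
    est <- basal_skew(out, basal_fraction)$angle_deg
    if (abs(est) < abs(best$est)) best <- list(total = total, est = est,
                                               mask = out)
    if (abs(est) <= tol) break
    total <- total + est
    out <- rotate_upright(mask, total)
  }
  # near the fixed point the estimate fluctuates at the rasterization
  # floor; scan a fine grid of poses around the best one and keep the pose
  # with the smallest measured residual
  if (abs(best$est) > tol) {
    base <- best$total
    for (off in seq(-0.3, 0.3, by = 0.06)) {
      if (off == 0) next
      cand <- rotate_upright(mask, base + off)
      est <- tryCatch(basal_skew(cand, basal_fraction)$angle_deg,
                      error = function(e) Inf)
      if (abs(est) < abs(best$est))
        best <- list(total = base + off, est = est, mask = cand)
    }
  }
  list(mask = best$mask, angle_deg = best$total, iterations = i,
       residual_deg = best$est)
}

#' Rotate a mask so the midrib is vertical
#'
#' Rotates by the negative of the estimated skew angle about the foreground
#' centroid with nearest-neighbour sampling, on a canvas expanded so no
#' foreground pixel is lost.
#'
#' @param mask 0/1 leaf mask.
#' @param skew A `leaf_skew` from [basal_skew()], or an angle in degrees.
#' @return Rotated mask.
#' @export
rotate_upright <- function(mask, skew) {
  assert_mask(mask)
  angle <- if (inherits(skew, "leaf_skew")) skew$angle_deg else skew
  assert_scalar_num(angle, "angle", -45, 45)
  if (angle == 0) return(mask)
  th <- -angle * pi / 180
  idx <- which(mask == 1L)
  nr <- nrow(mask); nc <- ncol(mask)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  ctr <- c(mean(rr), mean(cc))
  # rotation by th in (x = col, y = row): output extent from input corners
  corners <- rbind(c(1, 1), c(1, nc), c(nr, nc), c(nr, 1))
  rot_fwd <- function(p) {
    dy <- p[, 1L] - ctr[1L]; dx <- p[, 2L] - ctr[2L]
    cbind(ctr[1L] + dx * sin(th) + dy * cos(th),
          ctr[2L] + dx * cos(th) - dy * sin(th))
  }
  ext <- rot_fwd(corners)
  r_off <- floor(min(ext[, 1L])) - 1L
  c_off <- floor(min(ext[, 2L])) - 1L
  nr_out <- ceiling(max(ext[, 1L])) - r_off
  nc_out <- ceiling(max(ext[, 2L])) - c_off
  out_r <- rep(seq_len(nr_out), times = nc_out) + r_off
  out_c <- rep(seq_len(nc_out), each = nr_out) + c_off
  dy <- out_r - ctr[1L]; dx <- out_c - ctr[2L]
  src_r <- round(ctr[1L] - dx * sin(th) + dy * cos(th))
  src_c <- round(ctr[2L] + dx * cos(th) + dy * sin(th))
  ok <- src_r >= 1 & src_r <= nr & src_c >= 1 & src_c <= nc
  vals <- integer(nr_out * nc_out)
  vals[ok] <- mask[cbind(src_r[ok], src_c[ok])]
  out <- matrix(vals, nr_out, nc_out)
  attr(out, "foreground") <- attr(mask, "foreground")
  out
}
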