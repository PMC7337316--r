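# Synthetic leaf-on-sheet scene generator. Every downstream stage of the
# measurement pipeline is validated against scenes produced here, because the
# generator knows the exact landmark positions, dimensions, tilt and
# projective warp that the pipeline must recover.
#
# Geometry (cm, before tilt/warp): midrib on the vertical axis, y increasing
# downward; apex landmark at (x = 0, y = 0), petiole insertion at (0, L).
# A concave apex carves a cosine notch of depth `notch_depth_cm` into a flat
# shoulder band, so the flanking lobes rise above the landmark; a concave
# base mirrors this below the insertion. The lamina tapers into a narrow
# straight-flanked basal neck (the silhouette analogue of the straight basal
# midvein), which is what makes silhouette-midpoint skew estimation valid.

#' Specify a synthetic leaf shape
#'
#' @param length_cm Apex-to-insertion distance along the midrib (cm).
#' @param width_cm Maximum lamina width perpendicular to the midrib (cm).
#' @param apex,base `"convex"` or `"concave"`. A concave apex has a notch
#'   whose lowest point is the tip landmark; a concave base has a basal sinus
#'   whose highest point is the insertion landmark.
#' @param notch_depth_cm Depth of the apex notch (cm); must be 0 for a convex
#'   apex and less than `length_cm / 4`.
#' @param sinus_depth_cm Depth of the basal sinus (cm); same constraints.
#' @param seed Integer seed controlling the randomized outline coefficients
#'   (curvature exponents, shoulder extent, neck slope).
#' @param length_range,width_range Permitted ranges (cm); defaults cover the
#'   span reported for field-collected kiwifruit leaves.
#' @return A `leaf_shape` object.
#' @export
leaf_shape <- function(length_cm, width_cm,
                       apex = c("convex", "concave"),
                       base = c("convex", "concave"),
                       notch_depth_cm = 0, sinus_depth_cm = 0, seed = 1L,
                       length_range = c(3.6, 23.3),
                       width_range = c(3.5, 23.6)) {
  apex <- match.arg(apex)
  base <- match.arg(base)
  assert_scalar_num(length_cm, "length_cm", length_range[1], length_range[2])
  assert_scalar_num(width_cm, "width_cm", width_range[1], width_range[2])
  assert_scalar_num(notch_depth_cm, "notch_depth_cm", 0, Inf)
  assert_scalar_num(sinus_depth_cm, "sinus_depth_cm", 0, Inf)
  if (apex == "convex" && notch_depth_cm != 0)
    abort("convex apex requires notch_depth_cm = 0")
  if (base == "convex" && sinus_depth_cm != 0)
    abort("convex base requires sinus_depth_cm = 0")
  if (apex == "concave" && notch_depth_cm <= 0)
    abort("concave apex requires notch_depth_cm > 0")
  if (base == "concave" && sinus_depth_cm <= 0)
    abort("concave base requires sinus_depth_cm > 0")
  if (notch_depth_cm >= length_cm / 4 || sinus_depth_cm >= length_cm / 4)
    abort("notch/sinus depth must be < length_cm / 4")
  structure(list(length_cm = length_cm, width_cm = width_cm,
                 apex = apex, base = base,
                 notch_depth_cm = notch_depth_cm,
                 sinus_depth_cm = sinus_depth_cm, seed = as.integer(seed)),
            class = "leaf_shape")
}

# Seed-derived outline coefficients; deterministic per shape.
outline_params <- function(shape) {
  with_seed(shape$seed + 77L, {
    L <- shape$length_cm; W <- shape$width_cm
    p <- list(
      y_m       = runif(1, 0.35, 0.45) * L,   # widest row, from apex landmark
      ca        = runif(1, 0.55, 0.80),       # convex apex roundness
      pa        = runif(1, 1.6, 2.4),         # concave apex flank exponent
      pb        = runif(1, 0.45, 0.55),       # lower lamina curve exponent
                                              # (< 1: rounded side tips)
      f_a       = runif(1, 0.30, 0.40),       # shoulder extent fraction
      tan_alpha = runif(1, 0.14, 0.18),       # basal neck flank slope
      h_b       = 0.35 * L,                   # basal neck height
      qb        = runif(1, 2.0, 2.6)          # convex-base taper exponent
    )
    p$x_f <- p$f_a * W / 2
    p$x_n <- max(0.15, min(0.5 * p$x_f, 0.6 * shape$notch_depth_cm))
    if (shape$apex == "convex") p$x_n <- 0
    if (shape$base == "concave") {
      # truncate base: a straight-flanked neck flares into two flat
      # shoulders with the sinus between them. Shoulders are wide enough
      # (>= ~0.35 cm each) for the modal-row rule; flanks stay straight so
      # silhouette midpoints track the midrib
      sh_w <- clamp(0.12 * W, 0.35, 0.6)
      p$x_sn <- max(0.15, min(0.6 * shape$sinus_depth_cm, 1.2 * sh_w))
      p$x_sf <- p$x_sn + sh_w
      p$x_b <- p$x_sf + p$tan_alpha * (p$h_b + shape$sinus_depth_cm)
    } else {
      # acute base: lamina tapers into a blunt narrow neck; the half-width
      # floor (cm) keeps it several pixels wide at field resolutions
      p$x_sf <- 0; p$x_sn <- 0
      p$x_b <- max(0.45, p$tan_alpha * p$h_b)
    }
    p
  })
}

outline_top_y <- function(x, shape, p) {
  W <- shape$width_cm; d_n <- shape$notch_depth_cm
  a <- abs(x)
  if (shape$apex == "convex") {
    u <- pmin(2 * a / W, 1)
    return(p$y_m * (1 - (1 - u^2)^p$ca))
  }
  y <- numeric(length(x))
  cap <- a <= p$x_n
  y[cap] <- -d_n + d_n * 0.5 * (1 + cos(pi * a[cap] / p$x_n))
  sh <- a > p$x_n & a <= p$x_f
  y[sh] <- -d_n
  fl <- a > p$x_f
  v <- (a[fl] - p$x_f) / (W / 2 - p$x_f)
  y[fl] <- -d_n + (p$y_m + d_n) * v^p$pa
  y
}

outline_bot_y <- function(x, shape, p) {
  W <- shape$width_cm; L <- shape$length_cm; d_s <- shape$sinus_depth_cm
  a <- abs(x)
  y <- numeric(length(x))
  lam <- a >= p$x_b
  v <- (W / 2 - a[lam]) / (W / 2 - p$x_b)
  y[lam] <- p$y_m + (L - p$h_b - p$y_m) * v^p$pb
  if (shape$base == "convex") {
    # blunt power-curve taper: narrow neck ending in a rounded insertion,
    # sturdy under nearest-neighbour resampling at field resolutions
    nk <- a < p$x_b
    y[nk] <- L - p$h_b * (a[nk] / p$x_b)^p$qb
  } else {
    fl <- a < p$x_b & a > p$x_sf
    y[fl] <- L - p$h_b +
      (p$x_b - a[fl]) * (p$h_b + d_s) / (p$x_b - p$x_sf)
    flat <- a <= p$x_sf & a > p$x_sn
    y[flat] <- L + d_s
    cap <- a <= p$x_sn
    y[cap] <- L + d_s - d_s * 0.5 * (1 + cos(pi * a[cap] / p$x_sn))
  }
  y
}

#' Generate a leaf outline polygon
#'
#' Produces a simple closed polygon (cm units, midrib vertical) whose apex
#' and insertion landmarks are separated by exactly `length_cm` and whose
#' horizontal extent is exactly `width_cm`. A concave extremity places the
#' landmark at the bottom of a notch (top of a sinus), below (above) the
#' flanking lobes by exactly the notch (sinus) depth.
#'
#' @param shape A [leaf_shape()].
#' @param n_points Approximate number of polygon vertices (at least 64; the
#'   returned polygon has at least this many).
#' @return A `leaf_outline`: list with `points` (tibble of `x_cm`, `y_cm` in
#'   vertex order), `apex_index`, `insertion_index`, `shape`.
#' @export
leaf_outline <- function(shape, n_points = 256L) {
  stopifnot(inherits(shape, "leaf_shape"))
  if (n_points < 64L) abort("n_points must be >= 64")
  p <- outline_params(shape)
  W <- shape$width_cm
  if (p$x_b >= W / 2 || (shape$apex == "concave" && p$x_n >= p$x_f) ||
      (shape$base == "concave" && p$x_sn >= p$x_sf) ||
      (shape$base == "convex" && p$y_m >= shape$length_cm - p$h_b))
    abort("incompatible notch/width combination: outline would self-intersect")
  nt <- max(32L, ceiling(n_points / 2))
  base_grid <- seq(-W / 2, W / 2, length.out = nt + 1L)
  top_brk <- c(0, p$x_n, -p$x_n, p$x_f, -p$x_f,
               if (p$x_n > 0) seq(-p$x_n, p$x_n, length.out = 15L))
  grid_top <- sort(unique(c(base_grid, top_brk)))
  bot_brk <- c(0, p$x_b, -p$x_b, p$x_sf, -p$x_sf, p$x_sn, -p$x_sn,
               if (p$x_sn > 0) seq(-p$x_sn, p$x_sn, length.out = 15L),
               if (p$x_b > 0) seq(-p$x_b, p$x_b, length.out = 15L))
  grid_bot <- sort(unique(c(base_grid, bot_brk)))
  top <- cbind(x = grid_top, y = outline_top_y(grid_top, shape, p))
  bot <- cbind(x = grid_bot, y = outline_bot_y(grid_bot, shape, p))
  # traverse top edge left to right, bottom edge right to left; the shared
  # extreme-width vertices appear once
  bot_rev <- bot[rev(seq_len(nrow(bot))), , drop = FALSE]
  bot_rev <- bot_rev[-c(1L, nrow(bot_rev)), , drop = FALSE]
  pts <- rbind(top, bot_rev)
  apex_index <- which(pts[, "x"] == 0 & seq_len(nrow(pts)) <= nrow(top))[1L]
  insertion_index <- nrow(top) + which(bot_rev[, "x"] == 0)[1L]
  structure(list(points = tibble(x_cm = pts[, "x"], y_cm = pts[, "y"]),
                 apex_index = apex_index, insertion_index = insertion_index,
                 shape = shape),
            class = "leaf_outline")
}

#' Specify a renderable leaf-on-sheet scene
#'
#' @param shape A [leaf_shape()].
#' @param paper_cm Sheet dimensions `c(width, height)` in cm.
#' @param px_per_cm Rendering resolution.
#' @param tilt_deg In-plane rotation of the midrib from vertical; positive
#'   tilts the apex to the right.
#' @param perspective_px 4 x 2 matrix of `(row, col)` pixel displacements
#'   applied to the sheet's corners (order TL, TR, BR, BL) to emulate a
#'   non-frontal viewing angle. Default: no distortion.
#' @param noise_sd Additive Gaussian sensor noise, sd on the 0-255 scale.
#' @param color_gradient Strength in `[0, 1]` of the lamina's vertical color
#'   gradient and low-frequency mottling (0 = flat color).
#' @param seed Integer seed for noise and coloration.
#' @return A `leaf_scene` specification.
#' @export
leaf_scene <- function(shape, paper_cm = c(21, 29), px_per_cm = 20,
                       tilt_deg = 0, perspective_px = NULL, noise_sd = 0,
                       color_gradient = 0.5, seed = 1L) {
  stopifnot(inherits(shape, "leaf_shape"))
  assert_scalar_num(px_per_cm, "px_per_cm", 1, Inf)
  assert_scalar_num(tilt_deg, "tilt_deg", -45, 45)
  assert_scalar_num(noise_sd, "noise_sd", 0, Inf)
  assert_scalar_num(color_gradient, "color_gradient", 0, 1)
  if (is.null(perspective_px)) perspective_px <- matrix(0, 4, 2)
  perspective_px <- matrix(as.numeric(perspective_px), 4, 2)
  structure(list(shape = shape, paper_cm = as.numeric(paper_cm),
                 px_per_cm = px_per_cm, tilt_deg = tilt_deg,
                 perspective_px = perspective_px, noise_sd = noise_sd,
                 color_gradient = color_gradient, seed = as.integer(seed)),
            class = "leaf_scene")
}

#' Render a scene to an RGB image with ground truth
#'
#' Renders the scene by transforming the leaf outline and sheet rectangle
#' into the final frame (tilt, then projective warp) and rasterizing, so
#' landmark ground truth is exact to the polygon vertex. Before noise, sheet
#' pixels have blue-channel values >= 200 and leaf pixels <= 120, giving the
#' bimodal blue histogram the segmentation stage relies on. Identical scene
#' specifications (including seeds) render byte-identical images.
#'
#' @param scene A [leaf_scene()].
#' @return A `leaf_render`: list with `image` (H x W x 3 integer array,
#'   0-255) and `truth` (length/width cm, landmark pixel positions, tilt,
#'   true homography, px_per_cm, the rasterized leaf mask, and the sheet's
#'   true corner positions).
#' @export
render_scene <- function(scene) {
  stopifnot(inherits(scene, "leaf_scene"))
  shape <- scene$shape
  s <- scene$px_per_cm
  L <- shape$length_cm
  wp <- round(scene$paper_cm[1] * s)
  hp <- round(scene$paper_cm[2] * s)
  margin <- ceiling(max(0.08 * max(wp, hp), 16))
  nr <- hp + 2L * margin
  nc <- wp + 2L * margin
  # sheet area corners (TL, TR, BR, BL) at pixel-area boundaries
  ideal <- cbind(row = c(margin + 0.5, margin + 0.5, margin + hp + 0.5,
                         margin + hp + 0.5),
                 col = c(margin + 0.5, margin + wp + 0.5, margin + wp + 0.5,
                         margin + 0.5))
  warped <- ideal + scene$perspective_px
  if (any(warped[, 1] < 1 | warped[, 1] > nr | warped[, 2] < 1 |
          warped[, 2] > nc))
    abort("warped sheet exits the frame; reduce perspective displacements")
  h_true <- dlt_homography(ideal, warped)

  ol <- leaf_outline(shape, n_points = 384L)
  th <- scene$tilt_deg * pi / 180
  xr <- ol$points$x_cm * cos(th) - (ol$points$y_cm - L / 2) * sin(th)
  yr <- ol$points$x_cm * sin(th) + (ol$points$y_cm - L / 2) * cos(th)
  pc_row <- margin + 0.5 + hp / 2
  pc_col <- margin + 0.5 + wp / 2
  leaf_px <- cbind(row = pc_row + yr * s, col = pc_col + xr * s)
  pad <- 0.4 * s
  if (min(leaf_px[, "row"]) < margin + 1 + pad ||
      max(leaf_px[, "row"]) > margin + hp - pad ||
      min(leaf_px[, "col"]) < margin + 1 + pad ||
      max(leaf_px[, "col"]) > margin + wp - pad)
    abort("leaf does not fit inside the sheet; shrink the leaf or the tilt")

  leaf_fin <- homography_apply(h_true, leaf_px)
  tip_px <- leaf_fin[ol$apex_index, ]
  ins_px <- leaf_fin[ol$insertion_index, ]
  leaf_mask <- rasterize_polygon(leaf_fin, nr, nc)
  paper_mask <- rasterize_polygon(warped, nr, nc)
  paper_only <- paper_mask == 1L & leaf_mask == 0L

  img <- render_colors(scene, leaf_mask, paper_only, h_true,
                       pc_row, pc_col, th, L, nr, nc)
  truth <- list(length_cm = L, width_cm = shape$width_cm,
                tip_px = c(row = unname(tip_px[1]), col = unname(tip_px[2])),
                insertion_px = c(row = unname(ins_px[1]),
                                 col = unname(ins_px[2])),
                tilt_deg = scene$tilt_deg, homography_true = h_true,
                px_per_cm = s, leaf_mask = leaf_mask,
                paper_corners = warped, paper_cm = scene$paper_cm,
                apex = shape$apex, base = shape$base,
                notch_depth_cm = shape$notch_depth_cm,
                sinus_depth_cm = shape$sinus_depth_cm)
  structure(list(image = img, truth = truth, scene = scene),
            class = "leaf_render")
}

# Fill background/sheet/leaf colors and add sensor noise. The lamina gets a
# vertical (apex-to-base) darkening plus low-frequency mottling computed in
# the leaf's own (untilted, unwarped) coordinates, so coloration follows the
# blade whatever the pose.
render_colors <- function(scene, leaf_mask, paper_only, h_true,
                          pc_row, pc_col, th, L, nr, nc) {
  g <- scene$color_gradient
  img <- array(0, dim = c(nr, nc, 3L))
  img[, , 1] <- 44; img[, , 2] <- 41; img[, , 3] <- 38
  pap <- which(paper_only)
  pr <- ((pap - 1L) %% nr) + 1L
  illum <- 1 - 0.04 * (pr - 1) / (nr - 1)
  for (ch in 1:3) {
    base <- c(247, 246, 242)[ch]
    plane <- img[, , ch]
    plane[pap] <- base * illum
    img[, , ch] <- plane
  }
  idx <- which(leaf_mask == 1L)
  if (length(idx)) {
    rows <- ((idx - 1L) %% nr) + 1L
    cols <- ((idx - 1L) %/% nr) + 1L
    back <- homography_apply(solve(h_true), cbind(rows, cols))
    s <- scene$px_per_cm
    xi <- (back[, 2] - pc_col) / s
    yi <- (back[, 1] - pc_row) / s
    xl <- xi * cos(th) + yi * sin(th)          # untilted leaf coords (cm)
    yl <- -xi * sin(th) + yi * cos(th) + L / 2
    t <- clamp(yl / L, 0, 1)
    mot <- with_seed(scene$seed + 13L, {
      f <- runif(4, 0.10, 0.30); ph <- runif(2, 0, 2 * pi)
      0.5 * sin(2 * pi * (f[1] * xl + f[2] * yl) + ph[1]) +
        0.5 * sin(2 * pi * (f[3] * xl - f[4] * yl) + ph[2])
    })
    vals <- list(clamp(78 - 20 * g * t + 10 * g * mot, 30, 120),
                 clamp(128 - 30 * g * t + 14 * g * mot, 60, 160),
                 clamp(96 - 38 * g * t + 10 * g * mot, 40, 115))
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[idx] <- vals[[ch]]
      img[, , ch] <- plane
    }
  }
  if (scene$noise_sd > 0) {
    img <- img + with_seed(scene$seed + 29L,
                           array(rnorm(length(img), 0, scene$noise_sd),
                                 dim = dim(img)))
  }
  array(as.integer(round(clamp(img, 0, 255))), dim = dim(img))
}

#' Draw random scene specifications emulating a field-collected image set
#'
#' Samples leaf dimensions, extremity morphology, tilt, mild perspective and
#' noise. Leaves that would not fit inside the sheet at their drawn tilt are
#' scaled down isotropically.
#'
#' @param n Number of scenes.
#' @param seed Master seed; scene draws and per-scene render seeds derive
#'   from it.
#' @param length_range,width_ratio Length range (cm) and width/length ratio
#'   range to sample from.
#' @param concave_frac Probability that each extremity (apex, base
#'   independently) is concave.
#' @param depth_frac Range of notch/sinus depth as a fraction of leaf length.
#' @param tilt_max Tilt sampled uniformly in `[-tilt_max, tilt_max]` degrees.
#' @param perspective_frac Corner displacements sampled uniformly within
#'   this fraction of the sheet's pixel width.
#' @param noise_sd,px_per_cm,paper_cm Passed to [leaf_scene()].
#' @return List of `leaf_scene` objects.
#' @export
random_scenes <- function(n, seed = 1L, length_range = c(4, 23),
                          width_ratio = c(0.7, 1.1), concave_frac = 0.5,
                          depth_frac = c(0.02, 0.10), tilt_max = 15,
                          perspective_frac = 0.04, noise_sd = 5,
                          px_per_cm = 20, paper_cm = c(21, 29)) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      L <- runif(1, length_range[1], length_range[2])
      W <- clamp(L * runif(1, width_ratio[1], width_ratio[2]), 3.5, 23)
      apex <- if (runif(1) < concave_frac) "concave" else "convex"
      base <- if (runif(1) < concave_frac) "concave" else "convex"
      d_n <- if (apex == "concave") L * runif(1, depth_frac[1], depth_frac[2]) else 0
      d_s <- if (base == "concave") L * runif(1, depth_frac[1], depth_frac[2]) else 0
      tilt <- runif(1, -tilt_max, tilt_max)
      # shrink so the tilted leaf (with notch/sinus overhangs) fits the sheet
      ext_v <- d_n + L + d_s
      tha <- abs(tilt) * pi / 180
      half_w <- (W / 2) * cos(tha) + (ext_v / 2) * sin(tha)
      half_h <- (W / 2) * sin(tha) + (ext_v / 2) * cos(tha)
      f <- min(1, (paper_cm[1] / 2 - 1.2) / half_w,
               (paper_cm[2] / 2 - 1.2) / half_h)
      if (f < 1) {
        L <- max(length_range[1], L * f); W <- max(3.5, W * f)
        d_n <- d_n * f; d_s <- d_s * f
      }
      mag <- perspective_frac * paper_cm[1] * px_per_cm
      shp <- leaf_shape(L, W, apex, base, d_n, d_s,
                        seed = sample.int(1e6, 1),
                        length_range = c(3.5, 24), width_range = c(3.4, 24))
      leaf_scene(shp, paper_cm = paper_cm, px_per_cm = px_per_cm,
                 tilt_deg = tilt,
                 perspective_px = matrix(runif(8, -mag, mag), 4, 2),
                 noise_sd = noise_sd,
                 color_gradient = runif(1, 0.4, 0.9),
                 seed = sample.int(1e6, 1))
    })
  })
}

#' Write rendered scenes to PNG files with a ground-truth manifest
#'
#' @param scenes List of `leaf_scene` objects (e.g. from [random_scenes()]).
#' @param dir Output directory (created if needed).
#' @return The manifest tibble (one row per scene: filename, dimensions,
#'   landmark pixels, tilt, resolution, morphology), also written to
#'   `manifest.csv` in `dir`.
#' @export
write_scenes <- function(scenes, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- purrr::imap(scenes, function(sc, i) {
    rnd <- render_scene(sc)
    fn <- sprintf("scene_%03d.png", i)
    png::writePNG(rnd$image / 255, file.path(dir, fn))
    tr <- rnd$truth
    tibble(filename = fn, length_cm = tr$length_cm, width_cm = tr$width_cm,
           tip_row = tr$tip_px["row"], tip_col = tr$tip_px["col"],
           insertion_row = tr$insertion_px["row"],
           insertion_col = tr$insertion_px["col"],
           tilt_deg = tr$tilt_deg, px_per_cm = tr$px_per_cm,
           apex = tr$apex, base = tr$base)
  })
  manifest <- purrr::list_rbind(rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
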