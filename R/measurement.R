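# Conversion of landmarks and mask geometry into physical leaf dimensions.
# Length is the Euclidean distance between tip and insertion; width is the
# widest horizontal row span of the de-skewed silhouette; both are scaled
# to centimetres using the sheet-derived pixels-per-centimetre.

#' Euclidean distance between two pixel positions
#'
#' @param a,b `(row, col)` coordinate pairs.
#' @return Distance in pixels.
#' @export
point_distance <- function(a, b) {
  sqrt(sum((as.numeric(a) - as.numeric(b))^2))
}

#' Widest-row width of a leaf mask
#'
#' For a de-skewed mask (midrib vertical), the leaf width is the inclusive
#' horizontal span between the two edge pixels of the widest row.
#'
#' @param mask 0/1 leaf mask.
#' @return List with `width_px` (integer span) and `widest_row` (smallest
#'   such row on ties).
#' @export
mask_width <- function(mask) {
  assert_mask(mask)
  if (sum(mask) == 0L) abort("mask has no foreground pixels")
  rows_fg <- which(rowSums(mask) > 0)
  spans <- vapply(rows_fg, function(r) {
    cc <- which(mask[r, ] == 1L)
    max(cc) - min(cc) + 1L
  }, integer(1))
  best <- which.max(spans)                 # first maximum = smallest row
  list(width_px = spans[best], widest_row = rows_fg[best])
}

#' Calibration scale from the rectified sheet
#'
#' Pixels-per-centimetre is the mean of the two independent estimates from
#' the sheet's rectified width and height. The two must agree within
#' `tol` (relative); disagreement signals a failed rectification.
#'
#' @param extent_px `c(height_px, width_px)` of the rectified sheet.
#' @param paper_cm `c(width_cm, height_cm)` physical sheet size.
#' @param tol Maximum relative disagreement between the two estimates.
#' @return A `leaf_scale`: list with `px_per_cm`, `paper_cm`, `extent_px`.
#' @export
calibrate_scale <- function(extent_px, paper_cm = c(21, 29), tol = 0.01) {
  if (any(paper_cm <= 0)) abort("paper dimensions must be positive")
  s_w <- extent_px[2L] / paper_cm[1L]
  s_h <- extent_px[1L] / paper_cm[2L]
  if (abs(s_w - s_h) / max(s_w, s_h) > tol)
    abort(sprintf(paste0("calibration estimates disagree (%.2f vs %.2f ",
                         "px/cm); rectification looks wrong"), s_w, s_h),
          class = "leafmetrics_bad_calibration")
  structure(list(px_per_cm = (s_w + s_h) / 2, paper_cm = paper_cm,
                 extent_px = extent_px),
            class = "leaf_scale")
}

#' Measure leaf length and width
#'
#' @param mask De-skewed, cleaned 0/1 leaf mask.
#' @param landmarks A `leaf_landmarks` from [find_landmarks()].
#' @param scale A `leaf_scale` from [calibrate_scale()].
#' @return One-row tibble: `length_px`, `width_px`, `length_cm`,
#'   `width_cm`, `widest_row`, `px_per_cm`, landmark coordinates and shape
#'   labels.
#' @export
measure_leaf <- function(mask, landmarks, scale) {
  stopifnot(inherits(landmarks, "leaf_landmarks"),
            inherits(scale, "leaf_scale"))
  len_px <- point_distance(landmarks$tip, landmarks$insertion)
  w <- mask_width(mask)
  s <- scale$px_per_cm
  tibble(length_px = len_px, width_px = as.numeric(w$width_px),
         length_cm = len_px / s, width_cm = w$width_px / s,
         widest_row = w$widest_row, px_per_cm = s,
         tip_row = unname(landmarks$tip["row"]),
         tip_col = unname(landmarks$tip["col"]),
         insertion_row = unname(landmarks$insertion["row"]),
         insertion_col = unname(landmarks$insertion["col"]),
         tip_shape = landmarks$tip_shape,
         base_shape = landmarks$base_shape)
}
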