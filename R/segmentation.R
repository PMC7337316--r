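# Blue-channel histogram-valley segmentation. White sheet and green lamina
# contrast most strongly in the blue channel, so the blue histogram of a
# valid scene is bimodal: a bright sheet mode at the right end and darker
# leaf/background mass to its left. The threshold is the valley between the
# two rightmost modes; pixels at or below it are leaf (ties go to leaf).

#' Extract the blue channel of an 8-bit RGB image
#'
#' @param image H x W x 3 array, values 0-255.
#' @return Integer matrix (H x W) with attribute `channel = "B"`.
#' @export
blue_channel <- function(image) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    abort("`image` must be an H x W x 3 RGB array")
  ch <- matrix(as.integer(image[, , 3L]), dim(image)[1], dim(image)[2])
  attr(ch, "channel") <- "B"
  ch
}

#' 3x3 median filter with edge replication
#'
#' Each output pixel is the median of its 3x3 neighbourhood; borders are
#' handled by replicating edge pixels so no spurious dark frame is
#' introduced into the histogram. Implemented as a vectorized 9-input
#' median network.
#'
#' @param channel Integer matrix.
#' @return Filtered matrix, same dimensions.
#' @export
median_filter3 <- function(channel) {
  if (!is.matrix(channel)) abort("`channel` must be a matrix")
  nr <- nrow(channel); nc <- ncol(channel)
  pad <- channel[c(1L, seq_len(nr), nr), c(1L, seq_len(nc), nc)]
  v <- vector("list", 9L)
  k <- 0L
  for (dr in 0:2) for (dc in 0:2) {
    k <- k + 1L
    v[[k]] <- as.numeric(pad[dr + seq_len(nr), dc + seq_len(nc)])
  }
  # median-of-9 exchange network (19 compare-exchange steps); xch puts the
  # minimum in slot i and the maximum in slot j
  xch <- function(i, j) {
    lo <- pmin(v[[i]], v[[j]]); hi <- pmax(v[[i]], v[[j]])
    v[[i]] <<- lo; v[[j]] <<- hi
  }
  xch(2, 3); xch(5, 6); xch(8, 9); xch(1, 2); xch(4, 5); xch(7, 8)
  xch(2, 3); xch(5, 6); xch(8, 9); xch(1, 4); xch(6, 9); xch(5, 8)
  xch(4, 7); xch(2, 5); xch(3, 6); xch(5, 8); xch(5, 3); xch(7, 5); xch(5, 3)
  out <- matrix(as.integer(v[[5]]), nr, nc)
  attr(out, "channel") <- attr(channel, "channel")
  out
}

#' Grey-level histogram of an 8-bit channel
#'
#' @param channel Integer matrix with values in 0-255.
#' @return A `gray_histogram`: list with `counts` (integer vector of length
#'   256, index v+1 counting pixels of value v) and `total`.
#' @export
gray_histogram <- function(channel) {
  counts <- tabulate(as.integer(channel) + 1L, nbins = 256L)
  structure(list(counts = counts, total = length(channel)),
            class = "gray_histogram")
}

#' Select the valley at the right end of a histogram as the threshold
#'
#' The counts are smoothed with a centred moving average, local maxima with
#' prominence of at least 1% of the pixel total are located, and the
#' threshold is the grey level minimizing the smoothed histogram strictly
#' between the two rightmost such modes (centre of the minimizing run on
#' ties). Fails with class `leafmetrics_no_valley` when fewer than two
#' prominent modes exist (e.g. a scene without a white sheet).
#'
#' @param hist A [gray_histogram()].
#' @param smooth_window Odd moving-average window (grey levels).
#' @param min_prominence Required mode prominence as a fraction of `total`.
#' @param min_separation Prominent maxima closer than this many grey levels
#'   are one mode (sampling noise can split a mode into equal-height twin
#'   peaks that prominence alone cannot demote); the taller, then the
#'   rightmost, survives. Far below the inter-mode gaps the method relies
#'   on.
#' @return Integer threshold in 0-255: leaf pixels satisfy `value <=`
#'   threshold, sheet pixels `value >` threshold.
#' @export
valley_threshold <- function(hist, smooth_window = 9L, min_prominence = 0.01,
                             min_separation = 20L) {
  stopifnot(inherits(hist, "gray_histogram"))
  if (smooth_window < 1L || smooth_window %% 2L == 0L)
    abort("smooth_window must be odd and >= 1")
  s <- smooth_counts(hist$counts, smooth_window)
  peaks <- find_peaks(s)
  prom <- peak_prominence(s, peaks)
  peaks <- peaks[prom >= min_prominence * hist$total]
  peaks <- merge_close_peaks(peaks, s, min_separation)
  if (length(peaks) < 2L)
    abort("histogram has fewer than two prominent modes; no valley to select",
          class = "leafmetrics_no_valley")
  p2 <- sort(peaks, decreasing = TRUE)[1:2]   # two rightmost modes
  lo <- min(p2); hi <- max(p2)
  seg <- s[(lo + 1L):(hi - 1L)]
  at <- which(seg == min(seg))
  thr_index <- lo + at[ceiling(length(at) / 2)]   # centre of the min run
  as.integer(thr_index - 1L)                      # 1-based index -> grey level
}

# Collapse clusters of prominent maxima closer than min_separation into
# their tallest member (ties to the rightmost).
merge_close_peaks <- function(peaks, s, min_separation) {
  if (length(peaks) < 2L) return(peaks)
  peaks <- sort(peaks)
  repeat {
    gaps <- diff(peaks)
    k <- which(gaps < min_separation)
    if (!length(gaps) || !length(k)) return(peaks)
    i <- k[1L]
    drop <- if (s[peaks[i]] > s[peaks[i + 1L]]) i + 1L else i
    peaks <- peaks[-drop]
  }
}

# Centred moving average; near the ends the window shrinks to what fits.
smooth_counts <- function(counts, window) {
  if (window == 1L) return(as.numeric(counts))
  half <- (window - 1L) %/% 2L
  kern <- rep(1, window)
  num <- as.numeric(stats::filter(c(rep(0, half), counts, rep(0, half)),
                                  kern, sides = 2L))[half + seq_along(counts)]
  den <- as.numeric(stats::filter(c(rep(0, half), rep(1, length(counts)),
                                    rep(0, half)),
                                  kern, sides = 2L))[half + seq_along(counts)]
  num / den
}

# Indices (1-based) of local maxima; a plateau yields its centre index.
find_peaks <- function(s) {
  n <- length(s)
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  out <- integer(0)
  for (i in seq_len(k)) {
    left_ok <- i == 1L || r$values[i - 1L] < r$values[i]
    right_ok <- i == k || r$values[i + 1L] < r$values[i]
    if (left_ok && right_ok && !(i == 1L && i == k))
      out <- c(out, starts[i] + (r$lengths[i] - 1L) %/% 2L)
  }
  out
}

# Topographic prominence of each peak within the smoothed histogram. The
# key-saddle base on each side is the minimum before the next higher value;
# a side with no samples does not constrain the prominence.
peak_prominence <- function(s, peaks) {
  side_base <- function(vals, h) {
    if (!length(vals)) return(-Inf)
    higher <- which(vals > h)
    if (length(higher)) {
      upto <- higher[1L] - 1L
      if (upto < 1L) h else min(vals[seq_len(upto)], h)
    } else min(vals)
  }
  n <- length(s)
  vapply(peaks, function(p) {
    h <- s[p]
    left <- if (p > 1L) rev(s[seq_len(p - 1L)]) else numeric(0)
    right <- if (p < n) s[(p + 1L):n] else numeric(0)
    h - max(side_base(left, h), side_base(right, h))
  }, numeric(1))
}

#' Threshold a channel into a leaf-foreground binary mask
#'
#' @param channel Integer matrix.
#' @param threshold Grey level in 0-255; pixels with `value <= threshold`
#'   become foreground (the leaf is darker than the sheet in blue).
#' @return Integer 0/1 matrix with attribute `foreground = "leaf"`.
#' @export
binarize <- function(channel, threshold) {
  assert_scalar_num(threshold, "threshold", 0, 255)
  mask <- matrix(as.integer(channel <= threshold), nrow(channel),
                 ncol(channel))
  attr(mask, "foreground") <- "leaf"
  mask
}
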