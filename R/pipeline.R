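# End-to-end orchestration: segmentation -> rectification -> cleaning ->
# de-skew -> landmarks -> measurement, with per-stage status so a
# disagreement with a manual measurement can be audited stage by stage.

#' Pipeline configuration
#'
#' @param paper_cm Physical sheet size `c(width, height)` in cm.
#' @param median_window Median filter window; the method uses 3 (3x3).
#' @param valley_smooth_window Odd moving-average window for histogram
#'   smoothing before valley selection.
#' @param basal_fraction Fraction of leaf rows used for the basal skew fit.
#' @param band_decile Extremity band depth for landmark search.
#' @param concave_threshold_px Concave/convex dispatch threshold (pixels).
#' @param debug_dir Optional directory for per-stage mask PNG dumps.
#' @param keep_intermediates Keep intermediate rasters in the run record
#'   (useful for diagnostics; off by default to save memory).
#' @return A `leaf_config` list.
#' @export
leaf_config <- function(paper_cm = c(21, 29), median_window = 3L,
                        valley_smooth_window = 9L, basal_fraction = 0.2,
                        band_decile = 0.1, concave_threshold_px = 3L,
                        debug_dir = NULL, keep_intermediates = FALSE) {
  if (median_window != 3L)
    abort("only the 3x3 median filter is supported (median_window = 3)")
  if (valley_smooth_window %% 2L == 0L || valley_smooth_window < 3L)
    abort("valley_smooth_window must be odd and >= 3")
  assert_scalar_num(basal_fraction, "basal_fraction", 0.01, 0.499)
  assert_scalar_num(band_decile, "band_decile", 0.01, 0.499)
  structure(list(paper_cm = as.numeric(paper_cm),
                 median_window = 3L,
                 valley_smooth_window = as.integer(valley_smooth_window),
                 basal_fraction = basal_fraction,
                 band_decile = band_decile,
                 concave_threshold_px = as.integer(concave_threshold_px),
                 debug_dir = debug_dir,
                 keep_intermediates = isTRUE(keep_intermediates)),
            class = "leaf_config")
}

#' Measure a leaf photograph end to end
#'
#' Runs the full chain: blue channel, 3x3 median filter, histogram-valley
#' threshold, binarization, sheet-corner rectification, crop, largest-
#' component cleaning, basal skew estimation and rotation, landmark
#' dispatch, and calibration to centimetres. Any stage failure yields a
#' structured failure record, never a partial measurement.
#'
#' @param x An H x W x 3 RGB array (0-255) or an image file path.
#' @param config A [leaf_config()].
#' @return A `leaf_run`: list with `ok`, `stages` (tibble of stage, status,
#'   detail), `measurement` (one-row tibble or `NULL`), `warnings`, and
#'   `diagnostics` (threshold, sheet corners, skew angle and residual,
#'   uncorrected width, landmark labels; intermediate masks when
#'   `keep_intermediates`).
#' @export
measure_image <- function(x, config = leaf_config()) {
  stopifnot(inherits(config, "leaf_config"))
  source_label <- if (is.character(x)) x else "<array>"
  stages <- list()
  warnings <- character(0)
  diag <- list()
  note <- function(stage, detail = "") {
    stages[[length(stages) + 1L]] <<- tibble(stage = stage, status = "ok",
                                             detail = detail)
  }
  add_warning <- function(msg) warnings <<- c(warnings, msg)
  dump <- function(stage_no, name, mask) {
    if (!is.null(config$debug_dir)) {
      if (!dir.exists(config$debug_dir))
        dir.create(config$debug_dir, recursive = TRUE)
      write_mask_png(mask, file.path(config$debug_dir,
                                     sprintf("%02d_%s.png", stage_no, name)))
    }
  }
  result <- withCallingHandlers(
    tryCatch({
      img <- if (is.character(x)) read_leaf_image(x) else x
      note("read", sprintf("%d x %d", dim(img)[1], dim(img)[2]))
      b <- blue_channel(img)
      note("blue_channel")
      bf <- median_filter3(b)
      note("median_filter")
      hist <- gray_histogram(bf)
      thr <- valley_threshold(hist, config$valley_smooth_window)
      diag$threshold <- thr
      note("valley_threshold", sprintf("threshold = %d", thr))
      leaf_raw <- binarize(bf, thr)
      # sheet geometry from the unfiltered binarization: the median filter
      # smooths staircase edges and would bias the sub-pixel corner fit
      paper_raw <- matrix(as.integer(b > thr), nrow(b), ncol(b))
      note("binarize")
      quad <- detect_paper_quad(paper_raw)
      diag$paper_quad <- quad
      note("detect_sheet", sprintf("corners at rows %.1f-%.1f",
                                   min(quad[, 1]), max(quad[, 1])))
      wpx <- (point_distance(quad[1, ], quad[2, ]) +
                point_distance(quad[4, ], quad[3, ])) / 2
      hpx <- (point_distance(quad[1, ], quad[4, ]) +
                point_distance(quad[2, ], quad[3, ])) / 2
      s_est <- mean(c(wpx / config$paper_cm[1], hpx / config$paper_cm[2]))
      target_w <- round(config$paper_cm[1] * s_est)
      target_h <- round(config$paper_cm[2] * s_est)
      h <- estimate_homography(quad, target_w, target_h)
      diag$homography <- h
      note("rectify", sprintf("target %d x %d px", target_h, target_w))
      rect <- warp_image(leaf_raw, h)
      dump(6, "rectified", rect)
      cropped <- crop_to_paper(rect)
      note("crop")
      clean <- keep_largest_component(cropped)
      dump(7, "cleaned", clean)
      note("clean", sprintf("%d foreground px", sum(clean)))
      dsk <- deskew_mask(clean, config$basal_fraction)
      upright <- dsk$mask
      diag$skew_deg <- dsk$angle_deg
      residual <- basal_skew(upright, config$basal_fraction)$angle_deg
      diag$skew_residual_deg <- residual
      dump(8, "deskewed", upright)
      note("deskew", sprintf("angle %.2f deg, residual %.2f deg",
                             dsk$angle_deg, residual))
      lm_ <- find_landmarks(upright, config$band_decile,
                            config$concave_threshold_px)
      if (lm_$near_threshold)
        add_warning("concave/convex decision within 1 px of threshold")
      note("landmarks", sprintf("tip %s, base %s", lm_$tip_shape,
                                lm_$base_shape))
      scale <- calibrate_scale(c(target_h, target_w), config$paper_cm)
      meas <- measure_leaf(upright, lm_, scale)
      diag$width_px_uncorrected <- mask_width(clean)$width_px
      diag$landmarks <- lm_
      if (config$keep_intermediates) {
        diag$mask_rectified <- rect
        diag$mask_cleaned <- clean
        diag$mask_upright <- upright
      }
      note("measure", sprintf("length %.2f cm, width %.2f cm",
                              meas$length_cm, meas$width_cm))
      list(ok = TRUE, measurement = meas)
    }, error = function(e) {
      stages[[length(stages) + 1L]] <<- tibble(
        stage = "failed", status = "error",
        detail = conditionMessage(e))
      list(ok = FALSE, measurement = NULL)
    }),
    warning = function(w) {
      add_warning(conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  structure(list(source = source_label, ok = result$ok,
                 stages = purrr::list_rbind(stages),
                 measurement = result$measurement,
                 warnings = warnings, diagnostics = diag,
                 config = config),
            class = "leaf_run")
}

#' @export
print.leaf_run <- function(x, ...) {
  cat(sprintf("leaf_run [%s]: %s\n", x$source,
              if (x$ok) "ok" else "FAILED"))
  if (x$ok)
    cat(sprintf("  length %.2f cm, width %.2f cm (tip %s, base %s)\n",
                x$measurement$length_cm, x$measurement$width_cm,
                x$measurement$tip_shape, x$measurement$base_shape))
  else cat("  ", utils::tail(x$stages$detail, 1L), "\n")
  invisible(x)
}

#' Measure a directory (or vector) of leaf photographs
#'
#' Processes every image, continuing past per-image failures. If a
#' ground-truth manifest is available (`manifest.csv` in the directory, or
#' passed directly), agreement reports for length and width are computed
#' against it.
#'
#' @param images Directory containing images, or a character vector of
#'   image paths.
#' @param config A [leaf_config()].
#' @param manifest Optional tibble/data.frame with columns `filename`,
#'   `length_cm`, `width_cm`.
#' @return A `leaf_batch`: list with `results` (one row per image; failed
#'   images carry `NA` measurements and the failure reason), `agreement`
#'   (list of `leaf_agreement` for length and width, or `NULL`), `n_ok`,
#'   `n_failed`.
#' @export
run_batch <- function(images, config = leaf_config(), manifest = NULL) {
  if (length(images) == 1L && dir.exists(images)) {
    dir <- images
    paths <- list.files(dir, pattern = "\\.(png|jpe?g|tiff?)$",
                        ignore.case = TRUE, full.names = TRUE)
    mf <- file.path(dir, "manifest.csv")
    if (is.null(manifest) && file.exists(mf))
      manifest <- utils::read.csv(mf)
  } else paths <- images
  paths <- paths[file.exists(paths)]
  if (!length(paths)) abort("no images to process")
  rows <- lapply(paths, function(p) {
    run <- measure_image(p, config)
    if (run$ok) {
      cbind(tibble(filename = basename(p), ok = TRUE, failure = NA_character_),
            run$measurement)
    } else {
      tibble(filename = basename(p), ok = FALSE,
             failure = utils::tail(run$stages$detail, 1L))
    }
  })
  results <- purrr::list_rbind(rows)
  agreement <- NULL
  if (!is.null(manifest) && any(results$ok)) {
    m <- merge(results[results$ok, ], manifest, by = "filename",
               suffixes = c("", "_true"))
    if (nrow(m) >= 2L) {
      agreement <- list(
        length = agreement_report(m$length_cm_true, m$length_cm,
                                  label = "length"),
        width = agreement_report(m$width_cm_true, m$width_cm,
                                 label = "width"))
    }
  }
  structure(list(results = results, agreement = agreement,
                 n_ok = sum(results$ok), n_failed = sum(!results$ok)),
            class = "leaf_batch")
}

#' @export
print.leaf_batch <- function(x, ...) {
  cat(sprintf("leaf_batch: %d measured, %d failed\n", x$n_ok, x$n_failed))
  if (!is.null(x$agreement)) {
    print(x$agreement$length)
    print(x$agreement$width)
  }
  invisible(x)
}
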