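# Sheet-corner detection, four-point rectification, cleaning, and basal
# skew correction.

test_that("corners of an axis-aligned rectangle are recovered", {
  m <- matrix(0L, 650, 490)
  m[51:610, 31:430] <- 1L
  q <- detect_paper_quad(m)
  expected <- rbind(c(50.5, 30.5), c(50.5, 430.5),
                    c(610.5, 430.5), c(610.5, 30.5))
  expect_lte(max(abs(q - expected)), 1)
})

test_that("corners of a projectively warped sheet match the true warp", {
  persp <- matrix(c(6, 4, -5, 7, 8, -6, -4, -8), 4, 2, byrow = TRUE)
  rnd <- render_scene(leaf_scene(std_shape(), perspective_px = persp,
                                 noise_sd = 0, seed = 11))
  b <- blue_channel(rnd$image)
  thr <- valley_threshold(gray_histogram(b))
  q <- detect_paper_quad(matrix(as.integer(b > thr), nrow(b), ncol(b)))
  expect_lte(max(sqrt(rowSums((q - rnd$truth$paper_corners)^2))), 1)
})

test_that("a dark frame yields an explicit no-sheet failure", {
  expect_error(detect_paper_quad(matrix(0L, 100, 100)),
               class = "leafmetrics_no_sheet")
})

test_that("four-point homography is exact and rejects degeneracy", {
  # identity case: quad already at the target rectangle
  q <- rbind(c(0.5, 0.5), c(0.5, 420.5), c(580.5, 420.5), c(580.5, 0.5))
  h <- estimate_homography(q, 420, 580)
  expect_lte(max(abs(h$matrix - diag(3))), 1e-9)
  # zero residual at the corners for a generic quad
  q2 <- rbind(c(30.2, 41.7), c(25.1, 460.8), c(630.9, 450.3), c(622.4, 35.6))
  h2 <- estimate_homography(q2, 420, 580)
  proj <- leafmetrics:::homography_apply(h2$matrix, q2)
  tgt <- rbind(c(0.5, 0.5), c(0.5, 420.5), c(580.5, 420.5), c(580.5, 0.5))
  expect_lte(max(abs(proj - tgt)), 1e-8)
  # collinear corners rejected
  bad <- rbind(c(0, 0), c(0, 100), c(0, 200), c(100, 0))
  expect_error(estimate_homography(bad, 100, 100), "degenerate")
})

test_that("estimated homography reproduces the renderer's true warp", {
  persp <- matrix(c(9, -3, -7, 5, 6, 8, -5, -6), 4, 2, byrow = TRUE)
  rnd <- render_scene(leaf_scene(std_shape(), perspective_px = persp,
                                 noise_sd = 5, seed = 23))
  b <- blue_channel(rnd$image)
  thr <- valley_threshold(gray_histogram(median_filter3(b)))
  q <- detect_paper_quad(matrix(as.integer(b > thr), nrow(b), ncol(b)))
  h <- estimate_homography(q, 420, 580)
  proj <- leafmetrics:::homography_apply(h$matrix, rnd$truth$paper_corners)
  tgt <- rbind(c(0.5, 0.5), c(0.5, 420.5), c(580.5, 420.5), c(580.5, 0.5))
  expect_lte(max(sqrt(rowSums((proj - tgt)^2))), 0.5)
})

test_that("warping is invertible to high mask overlap and preserves scale", {
  m <- std_render()$truth$leaf_mask
  q <- rbind(c(30.5, 40.5), c(25.5, 460.5), c(630.5, 450.5), c(622.5, 35.5))
  h <- estimate_homography(q, 420, 580)
  fwd <- warp_image(m, h)
  hinv <- structure(list(matrix = solve(h$matrix), target_w = ncol(m),
                         target_h = nrow(m)), class = "leaf_homography")
  back <- warp_image(fwd, hinv)
  expect_gte(jaccard(m, back), 0.98)
  # identity warp returns the input
  hid <- structure(list(matrix = diag(3), target_w = ncol(m),
                        target_h = nrow(m)), class = "leaf_homography")
  expect_equal(warp_image(m, hid), matrix(as.integer(m), nrow(m), ncol(m)),
               ignore_attr = TRUE)
})

test_that("rectifying a known sheet restores metric extent", {
  persp <- matrix(c(6, 4, -5, 7, 8, -6, -4, -8), 4, 2, byrow = TRUE)
  rnd <- render_scene(leaf_scene(std_shape(), perspective_px = persp,
                                 noise_sd = 0, seed = 31))
  run <- measure_image(rnd$image, leaf_config(keep_intermediates = TRUE))
  expect_true(run$ok)
  # rectified leaf column extent equals width_cm * px_per_cm within 2 px
  up <- run$diagnostics$mask_cleaned
  cols <- which(colSums(up) > 0)
  expect_lte(abs((max(cols) - min(cols) + 1) -
                   rnd$truth$width_cm * run$measurement$px_per_cm), 2)
})

test_that("cropping preserves interior leaves and warns when clipped", {
  m <- matrix(0L, 50, 50)
  m[20:30, 20:30] <- 1L
  cropped <- crop_to_paper(m, c(5, 45, 5, 45))
  expect_equal(sum(cropped), sum(m))
  expect_warning(crop_to_paper(m, c(5, 25, 5, 45)),
                 class = "leafmetrics_clipped_leaf")
})

test_that("cleaning keeps exactly the largest component", {
  m <- matrix(0L, 200, 200)
  m[50:149, 50:149] <- 1L          # 10,000 px leaf
  m[5, 5] <- 1L; m[190:191, 3] <- 1L; m[2, 150:153] <- 1L
  clean <- keep_largest_component(m)
  expect_equal(sum(clean), 10000)
  expect_equal(clean[5, 5], 0L)
  single <- matrix(0L, 10, 10); single[3:6, 3:6] <- 1L
  expect_equal(unclass(keep_largest_component(single)), single,
               ignore_attr = TRUE)
  expect_error(keep_largest_component(matrix(0L, 5, 5)), "no foreground")
})

test_that("an untilted symmetric leaf has zero estimated skew", {
  sk <- basal_skew(std_render()$truth$leaf_mask)
  expect_lte(abs(sk$angle_deg), 0.2)
  expect_gte(sk$support_rows, 10)
})

test_that("single-shot skew recovers rendered tilt with the right sign", {
  for (tilt in c(10, -15)) {
    rnd <- render_scene(leaf_scene(leaf_shape(12, 9, seed = 6),
                                   tilt_deg = tilt, noise_sd = 0,
                                   seed = 13))
    est <- basal_skew(rnd$truth$leaf_mask)$angle_deg
    expect_lte(abs(est - tilt), 0.5)
  }
})

test_that("rotation conserves foreground and restores verticality", {
  rnd <- render_scene(leaf_scene(std_shape(), tilt_deg = -10, noise_sd = 0,
                                 seed = 17))
  m <- rnd$truth$leaf_mask
  rot <- rotate_upright(m, basal_skew(m))
  expect_lte(abs(sum(rot) - sum(m)) / sum(m), 0.01)
  expect_lte(abs(principal_axis_deg(rot) -
                   principal_axis_deg(std_render()$truth$leaf_mask)), 0.5)
  expect_identical(rotate_upright(m, 0), m)
})

test_that("de-skew is idempotent", {
  rnd <- render_scene(leaf_scene(leaf_shape(12, 9, seed = 6),
                                 tilt_deg = 14, noise_sd = 0, seed = 19))
  d1 <- deskew_mask(rnd$truth$leaf_mask)
  again <- basal_skew(d1$mask)$angle_deg
  expect_lte(abs(again), 0.2)
})
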