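# Boundary tracing and concave/convex landmark localization.

test_that("boundary tracing counts perimeter pixels exactly", {
  m3 <- matrix(0L, 5, 5); m3[2:4, 2:4] <- 1L
  expect_equal(nrow(trace_boundary(m3)), 8)
  m10 <- matrix(0L, 14, 14); m10[3:12, 3:12] <- 1L
  expect_equal(nrow(trace_boundary(m10)), 36)
  expect_error(trace_boundary(matrix(0L, 4, 4)), "no foreground")
})

test_that("every trace point borders the background and the loop closes", {
  m <- std_render()$truth$leaf_mask
  trc <- trace_boundary(m)
  pad <- matrix(0L, nrow(m) + 2, ncol(m) + 2)
  pad[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  for (k in seq(1, nrow(trc), by = 37)) {
    r <- trc[k, 1] + 1L; c <- trc[k, 2] + 1L
    expect_equal(pad[r, c], 1L)
    expect_lt(pad[r - 1, c] + pad[r + 1, c] + pad[r, c - 1] + pad[r, c + 1],
              4L)
  }
  gap <- abs(trc[1, ] - trc[nrow(trc), ])
  expect_lte(max(gap), 1)                      # endpoints are 8-neighbours
  steps <- abs(diff(trc[, 1])) + abs(diff(trc[, 2]))
  expect_true(all(steps >= 1))                 # no duplicate consecutive pts
  expect_true(all(abs(diff(trc[, 1])) <= 1 & abs(diff(trc[, 2])) <= 1))
})

test_that("tracing is deterministic", {
  m <- std_render()$truth$leaf_mask
  expect_identical(trace_boundary(m), trace_boundary(m))
})

test_that("the extremity segment spans the notch", {
  m <- std_render()$truth$leaf_mask        # 1 cm apex notch at 20 px/cm
  trc <- trace_boundary(m)
  seg <- select_band_segment(trc, "top")
  tip <- std_render()$truth$tip_px
  d <- sqrt((seg$points[, 1] - tip["row"])^2 +
              (seg$points[, 2] - tip["col"])^2)
  expect_lte(min(d), 1.5)                  # true notch pixel inside segment
  expect_lte(nrow(seg$points), nrow(trc) / 2 + 1)
})

test_that("difference curve reflects notch depth and flat extrema", {
  m <- std_render()$truth$leaf_mask
  trc <- trace_boundary(m)
  seg <- select_band_segment(trc, "top")
  cur <- difference_curve(seg, trc)
  expect_true(any(cur$offsets == 0))
  expect_lte(abs(max(cur$offsets) - 20), 2)  # 1 cm notch at 20 px/cm
  # flat segment at the extremum row gives an all-zero curve
  flat <- matrix(0L, 10, 20); flat[4:7, 5:15] <- 1L
  ftr <- trace_boundary(flat)
  fseg <- select_band_segment(ftr, "top")
  expect_true(all(difference_curve(fseg, ftr)$offsets == 0))
})

test_that("concave peak location follows the argmax with midline
           tie-breaks", {
  seg <- structure(list(points = cbind(row = c(10, 13, 17, 30, 16, 11),
                                       col = 21:26),
                        endpoint_a = c(10, 21), endpoint_b = c(11, 26),
                        band = "top"),
                   class = "edge_segment")
  cur <- structure(list(offsets = c(0, 3, 7, 20, 6, 1), reference_row = 10),
                   class = "difference_curve")
  expect_equal(unname(locate_concave_point(cur, seg)), c(30, 24))
  # two equal maxima: the one nearer the horizontal midpoint wins
  cur2 <- structure(list(offsets = c(0, 20, 7, 7, 20, 1), reference_row = 10),
                    class = "difference_curve")
  seg2 <- seg; seg2$points[, "col"] <- c(10, 12, 20, 24, 34, 36)
  expect_equal(unname(locate_concave_point(cur2, seg2)[2]), 12)
})

test_that("convex landmarks sit at global extrema with centroid
           tie-breaks", {
  sq <- matrix(0L, 9, 21); sq[3:7, 4:18] <- 1L
  pts <- locate_convex_points(trace_boundary(sq))
  expect_equal(unname(pts$tip[1]), 3)
  expect_equal(unname(pts$insertion[1]), 7)
  expect_lte(abs(pts$tip[2] - 11), 1)        # near the column centroid
})

test_that("extremity classification dispatches by notch depth", {
  expect_equal(classify_extremity(trace_boundary(
    convex_render()$truth$leaf_mask), "top"), "convex")
  expect_equal(classify_extremity(trace_boundary(
    std_render()$truth$leaf_mask), "top"), "concave")
  # sub-threshold notch falls back to convex
  tiny <- render_scene(leaf_scene(
    leaf_shape(10, 8, "concave", "convex", notch_depth_cm = 0.05, seed = 3),
    noise_sd = 0, seed = 5))
  expect_equal(classify_extremity(trace_boundary(tiny$truth$leaf_mask),
                                  "top"), "convex")
})

test_that("landmark dispatch recovers morphology and location", {
  rnd <- std_render()                       # concave apex, convex base
  lm <- find_landmarks(rnd$truth$leaf_mask)
  expect_equal(lm$tip_shape, "concave")
  expect_equal(lm$base_shape, "convex")
  expect_lte(sqrt(sum((lm$tip - rnd$truth$tip_px)^2)), 3)
  expect_lte(sqrt(sum((lm$insertion - rnd$truth$insertion_px)^2)), 2)
  cv <- convex_render()
  lmc <- find_landmarks(cv$truth$leaf_mask)
  expect_equal(lmc$tip_shape, "convex")
  expect_equal(lmc$base_shape, "convex")
  td <- tidy(lm)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$tip_shape, "concave")
})

test_that("landmarks are within tolerance across random morphologies", {
  withr::with_seed(1203, {
    for (k in 1:12) {
      L <- runif(1, 5, 20)
      W <- max(3.5, min(19, L * runif(1, 0.75, 1.05)))
      apex <- sample(c("concave", "convex"), 1)
      base <- sample(c("concave", "convex"), 1)
      dn <- if (apex == "concave") max(0.3, 0.06 * L) else 0
      ds <- if (base == "concave") max(0.3, 0.06 * L) else 0
      sh <- leaf_shape(L, W, apex, base, dn, ds, seed = k)
      rnd <- render_scene(leaf_scene(sh, noise_sd = 5, seed = k + 50))
      lm <- find_landmarks(rnd$truth$leaf_mask)
      tol_tip <- if (apex == "concave") 3 else 2
      tol_ins <- if (base == "concave") 3 else 2
      expect_lte(sqrt(sum((lm$tip - rnd$truth$tip_px)^2)), tol_tip)
      expect_lte(sqrt(sum((lm$insertion - rnd$truth$insertion_px)^2)),
                 tol_ins)
      expect_equal(lm$tip_shape, apex)
      expect_equal(lm$base_shape, base)
    }
  })
})

test_that("segment-restricted peak equals exhaustive decile search", {
  withr::with_seed(77, {
    for (k in 1:8) {
      L <- runif(1, 6, 20)
      W <- max(3.5, min(19, L * runif(1, 0.8, 1.05)))
      dn <- max(0.3, runif(1, 0.02, 0.10) * L)
      ds <- max(0.3, runif(1, 0.02, 0.10) * L)
      sh <- leaf_shape(L, W, "concave", "concave", dn, ds, seed = k)
      rnd <- render_scene(leaf_scene(sh, noise_sd = 0, seed = k + 30))
      m <- rnd$truth$leaf_mask
      trc <- trace_boundary(m)
      for (band in c("top", "bottom")) {
        seg <- select_band_segment(trc, band)
        p <- locate_concave_point(difference_curve(seg, trc), seg)
        bf <- brute_concave(m, band)
        expect_equal(unname(p), unname(bf))
      }
    }
  })
})

test_that("landmark extraction is deterministic", {
  m <- std_render()$truth$leaf_mask
  expect_identical(find_landmarks(m), find_landmarks(m))
})
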