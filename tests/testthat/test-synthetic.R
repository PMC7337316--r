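# Ground-truthed scene generator: outline geometry, rendering contracts,
# determinism.

test_that("shape specification enforces its geometric constraints", {
  expect_error(leaf_shape(10, 8, "convex", "convex", notch_depth_cm = 1),
               "notch_depth")
  expect_error(leaf_shape(10, 8, "concave", "convex"), "notch_depth")
  expect_error(leaf_shape(10, 8, "concave", "convex", notch_depth_cm = 3),
               "length_cm / 4")
  expect_error(leaf_shape(30, 8), "length_cm")
  expect_s3_class(leaf_shape(10, 8, "concave", "concave", 0.5, 0.5),
                  "leaf_shape")
})

test_that("outline separates landmarks by exactly the leaf length", {
  for (spec in list(leaf_shape(10, 8, seed = 1),
                    leaf_shape(18, 16, "concave", "concave", 1.2, 0.9,
                               seed = 4),
                    leaf_shape(4.5, 3.6, "concave", "convex", 0.4, 0,
                               seed = 9))) {
    ol <- leaf_outline(spec, 256)
    apex <- unlist(ol$points[ol$apex_index, ])
    ins <- unlist(ol$points[ol$insertion_index, ])
    expect_equal(unname(ins["y_cm"] - apex["y_cm"]), spec$length_cm)
    expect_equal(unname(apex["x_cm"]), 0)
    expect_equal(unname(ins["x_cm"]), 0)
    expect_equal(diff(range(ol$points$x_cm)), spec$width_cm)
  }
})

test_that("a concave apex places the landmark below the flanking lobes", {
  ol <- leaf_outline(leaf_shape(10, 8, "concave", "convex", 1, seed = 3))
  apex_y <- ol$points$y_cm[ol$apex_index]
  expect_lt(min(ol$points$y_cm), apex_y)          # lobes rise above landmark
  expect_equal(apex_y - min(ol$points$y_cm), 1)   # by exactly the notch depth
})

test_that("outline area matches the shoelace oracle and plausible coverage", {
  ol <- leaf_outline(leaf_shape(10, 8, seed = 3), 256)
  x <- ol$points$x_cm; y <- ol$points$y_cm
  n <- length(x); j <- c(n, seq_len(n - 1))
  shoelace <- abs(sum(x[j] * y - x * y[j])) / 2
  expect_gte(shoelace, 0.4 * 80)
  expect_lte(shoelace, 1.0 * 80)
  expect_gte(nrow(ol$points), 256)
})

test_that("rendered scenes honour the blue-channel separation contract", {
  rnd <- std_render()
  b <- rnd$image[, , 3]
  leaf <- rnd$truth$leaf_mask == 1L
  expect_lte(max(b[leaf]), 120)
  # bright sheet pixels dominate and sit above 200
  expect_gt(sum(b >= 200), 0.5 * length(b))
  expect_true(all(b[leaf] >= 0))
})

test_that("rendered mask extent matches width times resolution", {
  m <- std_render()$truth$leaf_mask
  cols <- which(colSums(m) > 0)
  expect_lte(abs((max(cols) - min(cols) + 1) - 160), 1)
})

test_that("identical scene specifications render byte-identical images", {
  sc <- leaf_scene(std_shape(), noise_sd = 5, tilt_deg = 7, seed = 99)
  r1 <- render_scene(sc)
  r2 <- render_scene(sc)
  expect_identical(r1$image, r2$image)
  expect_identical(r1$truth$tip_px, r2$truth$tip_px)
})

test_that("ground-truth landmarks sit on the mask boundary at the right
           separation", {
  for (rnd in list(std_render(), convex_render())) {
    tr <- rnd$truth
    d <- sqrt(sum((tr$tip_px - tr$insertion_px)^2)) / tr$px_per_cm
    expect_lte(abs(d - tr$length_cm), 2 / tr$px_per_cm)
    m <- tr$leaf_mask
    for (p in list(tr$tip_px, tr$insertion_px)) {
      r <- round(p["row"]); c <- round(p["col"])
      patch <- m[(r - 1):(r + 1), (c - 1):(c + 1)]
      expect_gt(sum(patch), 0)          # touches leaf
      expect_lt(sum(patch), 9)          # and background: a boundary point
    }
  }
})

test_that("rendered tilt matches an independent second-moments axis", {
  rnd <- render_scene(leaf_scene(std_shape(), tilt_deg = 10, noise_sd = 0,
                                 seed = 3))
  expect_lte(abs(principal_axis_deg(rnd$truth$leaf_mask) - 10), 0.5)
})

test_that("blue-channel histogram of a rendered scene has well-separated
           modes", {
  for (noise in c(0, 5, 10)) {
    rnd <- render_scene(leaf_scene(std_shape(), noise_sd = noise, seed = 11))
    h <- gray_histogram(blue_channel(rnd$image))
    s <- leafmetrics:::smooth_counts(h$counts, 9L)
    pk <- leafmetrics:::find_peaks(s)
    pk <- pk[leafmetrics:::peak_prominence(s, pk) >= 0.01 * h$total]
    expect_gte(length(pk), 2)
    two <- sort(pk, decreasing = TRUE)[1:2]
    expect_gte(abs(diff(two)), 80)
  }
})

test_that("landmark separation error shrinks as resolution grows", {
  errs <- vapply(c(10, 20, 40), function(ppcm) {
    rnd <- render_scene(leaf_scene(std_shape(), px_per_cm = ppcm, seed = 2))
    tr <- rnd$truth
    abs(sqrt(sum((tr$tip_px - tr$insertion_px)^2)) / ppcm - tr$length_cm)
  }, numeric(1))
  expect_lte(errs[3], 2 / 40)
  expect_true(all(errs <= 2 / c(10, 20, 40)))
})

test_that("scenes whose warped sheet exits the frame are rejected", {
  expect_error(
    render_scene(leaf_scene(std_shape(),
                            perspective_px = matrix(-500, 4, 2))),
    "exits the frame")
})

test_that("leaves too large for the sheet are rejected", {
  expect_error(render_scene(leaf_scene(leaf_shape(23, 22, seed = 1))),
               "fit inside")
})

test_that("scene writer produces PNGs and a consistent manifest", {
  dir <- withr::local_tempdir()
  scenes <- random_scenes(2, seed = 5, noise_sd = 0)
  manifest <- write_scenes(scenes, dir)
  expect_equal(nrow(manifest), 2)
  expect_true(all(file.exists(file.path(dir, manifest$filename))))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  img <- read_leaf_image(file.path(dir, manifest$filename[1]))
  rnd <- render_scene(scenes[[1]])
  expect_identical(img, rnd$image)
})
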