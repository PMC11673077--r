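test_that("extract_vessel_region finds the largest 8-connected component", {
  m <- rect_mask(8, 8, 2:6, 2:6)                      # 5x5 PA square
  expect_equal(extract_vessel_region(m, 1)$n_pixels, 25)

  m2 <- rect_mask(20, 20, 2:6, 2:7)                   # 30-px component
  m2[12:13, 10:14] <- 1L                              # 10-px component
  reg <- extract_vessel_region(m2, 1)
  expect_equal(reg$n_pixels, 30)
  expect_true(all(reg$pixels[, "row"] <= 5))          # the 30-px block kept

  # diagonal touch is connected under 8-connectivity
  m3 <- matrix(0L, 6, 6); m3[1, 1] <- 1L; m3[2, 2] <- 1L; m3[3, 3] <- 1L
  expect_equal(extract_vessel_region(m3, 1)$n_pixels, 3)

  expect_error(extract_vessel_region(m, 2), class = "missing_vessel")
})

test_that("equal-size component ties break on the topmost-then-leftmost anchor", {
  m <- matrix(0L, 12, 12)
  m[8:9, 8:9] <- 1L     # lower-right 2x2
  m[2:3, 2:3] <- 1L     # upper-left 2x2 (should win the tie)
  reg <- extract_vessel_region(m, 1)
  expect_equal(reg$n_pixels, 4)
  expect_equal(min(reg$pixels[, "row"]), 1)  # 0-based rows of the 2:3 block
})

test_that("principal axis follows the long side and flags near-circular regions", {
  wide <- extract_vessel_region(rect_mask(10, 30, 4:7, 5:24), 1)   # 4 x 20
  ax <- principal_axis(wide)
  expect_equal(ax$direction, c(0, 1), tolerance = 1e-12)
  expect_gt(ax$anisotropy, 1)
  expect_false(ax$near_degenerate)

  tall <- extract_vessel_region(rect_mask(30, 10, 5:24, 4:7), 1)   # 20 x 4
  expect_equal(principal_axis(tall)$direction, c(1, 0), tolerance = 1e-12)

  disk <- rasterize_ellipse(ellipse_spec(c(20, 20), 10, 10, 0, 1L), c(41, 41))
  axd <- principal_axis(disk)
  expect_equal(axd$anisotropy, 1, tolerance = 0.05)
  expect_true(axd$near_degenerate)
  expect_equal(sqrt(sum(axd$direction^2)), 1, tolerance = 1e-12)

  one <- structure(list(class_code = 1L, pixels = cbind(row = 0L, col = 0L),
                        n_pixels = 1L), class = "vessel_region")
  expect_error(principal_axis(one), class = "degenerate_region")
})

test_that("perpendicular diameter matches closed-form shapes", {
  # pixel centers spanning rows 0..19, cols 0..9; axis along the 20-side
  reg <- extract_vessel_region(rect_mask(22, 12, 1:20, 1:10), 1)
  ax <- principal_axis(reg)
  expect_equal(ax$direction, c(1, 0), tolerance = 1e-12)
  d <- perpendicular_diameter(reg, ax, tol_px = 0.5)
  expect_equal(d$length_px, 9.0)
  # endpoints really are perpendicular to the axis within tolerance
  expect_lte(abs(sum((d$a - d$b) * ax$direction)), 0.5)

  disk <- rasterize_ellipse(ellipse_spec(c(20, 20), 10, 10, 0, 1L), c(41, 41))
  dd <- perpendicular_diameter(disk, principal_axis(disk))$length_px
  expect_gte(dd, 19); expect_lte(dd, 20)

  ell <- rasterize_ellipse(ellipse_spec(c(40, 40), 30, 12, 30, 1L), c(81, 81))
  de <- perpendicular_diameter(ell, principal_axis(ell))$length_px
  expect_equal(de, 24, tolerance = 2 / 24)

  # extent-correction convention adds exactly 1 px
  expect_equal(perpendicular_diameter(reg, ax, extent_correction = TRUE)$length_px,
               10.0)
})

test_that("diameter oracle handles the trivial and degenerate pair sets", {
  two <- structure(list(class_code = 1L,
                        pixels = cbind(row = c(0L, 0L), col = c(0L, 5L)),
                        n_pixels = 2L), class = "vessel_region")
  axis_row <- structure(list(direction = c(1, 0), centroid = c(0, 2.5),
                             anisotropy = Inf, near_degenerate = FALSE),
                        class = "vessel_axis")
  expect_equal(diameter_oracle(two, axis_row), 5.0)
  expect_equal(perpendicular_diameter(two, axis_row)$length_px, 5.0)

  one <- structure(list(class_code = 1L, pixels = cbind(row = 0L, col = 0L),
                        n_pixels = 1L), class = "vessel_region")
  expect_error(diameter_oracle(one, axis_row), class = "degenerate_region")
  expect_error(perpendicular_diameter(one, axis_row), class = "degenerate_region")

  # no admissible pair: two pixels along the axis direction
  along <- structure(list(class_code = 1L,
                          pixels = cbind(row = c(0L, 5L), col = c(0L, 0L)),
                          n_pixels = 2L), class = "vessel_region")
  expect_error(perpendicular_diameter(along, axis_row), class = "degenerate_region")
})

test_that("sweep and oracle agree exactly on random blobs", {
  for (s in 1:30) {
    n <- withr::with_seed(1000 + s, sample(5:800, 1))
    reg <- random_blob(n, seed = s)
    ax <- principal_axis(reg)
    expect_identical(perpendicular_diameter(reg, ax)$length_px,
                     diameter_oracle(reg, ax))
  }
})

test_that("diameter is stable under 90-degree rotation and scale covariant", {
  m <- matrix(0L, 81, 81)
  ell <- rasterize_ellipse(ellipse_spec(c(40, 40), 25, 11, 25, 1L), c(81, 81))
  m[ell$pixels + 1L] <- 1L
  meas <- function(mm) {
    r <- extract_vessel_region(mm, 1)
    perpendicular_diameter(r, principal_axis(r))$length_px
  }
  base <- meas(m)
  cur <- m
  for (k in 1:3) {
    cur <- rot90(cur)
    expect_lte(abs(meas(cur) - base), 1)
  }
  # integer upscale: extent-convention diameters scale by k within 2 px
  # (center-to-center lengths pick up an extra k - 1 px of pixel extent,
  # which is why the extensive convention is the right one to test here)
  meas_ext <- function(mm) {
    r <- extract_vessel_region(mm, 1)
    perpendicular_diameter(r, principal_axis(r),
                           extent_correction = TRUE)$length_px
  }
  upscale <- function(mm, k) {
    u <- matrix(0L, k * nrow(mm), k * ncol(mm))
    u[] <- mm[(row(u) - 1) %/% k + 1 + ((col(u) - 1) %/% k) * nrow(mm)]
    u
  }
  base_ext <- meas_ext(m)
  for (k in 2:3)
    expect_lte(abs(meas_ext(upscale(m, k)) - k * base_ext), 2)
  # the PA/Ao ratio of a frame is invariant to uniform scaling within 0.05
  fr <- generate_phantom_frame(ellipse_spec(c(30, 25), 16, 12, 20, 1L),
                               ellipse_spec(c(30, 70), 14, 10, 100, 2L),
                               canvas = c(61, 101))
  r0 <- measure_frame(fr$mask)$ratio
  for (k in 2:3)
    expect_lte(abs(measure_frame(upscale(fr$mask, k))$ratio - r0), 0.05)
})

test_that("diameter never exceeds the bounding-box diagonal", {
  for (s in 1:10) {
    reg <- random_blob(withr::with_seed(s, sample(10:400, 1)), seed = 50 + s)
    ax <- principal_axis(reg)
    d <- perpendicular_diameter(reg, ax)$length_px
    bb <- apply(reg$pixels, 2, range)
    expect_lte(d, sqrt(sum((bb[2, ] - bb[1, ])^2)) + 1e-9)
  }
})

test_that("rasterized ellipses recover 2b within 2 px", {
  for (s in 1:20) {
    prm <- withr::with_seed(200 + s,
      list(b = runif(1, 5, 18), asp = runif(1, 1, 2), th = runif(1, 0, 180)))
    a <- prm$b * prm$asp
    cv <- 2 * ceiling(a) + 11
    reg <- rasterize_ellipse(
      ellipse_spec(c((cv - 1) / 2, (cv - 1) / 2), a, prm$b, prm$th, 1L),
      c(cv, cv))
    d <- perpendicular_diameter(reg, principal_axis(reg))$length_px
    expect_lte(abs(d - 2 * prm$b), 2)
  }
})

test_that("measure_frame yields ratios and propagates missing vessels", {
  fr <- generate_phantom_frame(ellipse_spec(c(30, 25), 16, 12, 20, 1L),
                               ellipse_spec(c(30, 70), 14, 10, 100, 2L),
                               canvas = c(61, 101))
  meas <- measure_frame(fr$mask)
  expect_equal(meas$ratio, 1.2, tolerance = 0.1 / 1.2)
  expect_true(is.na(meas$svc_px))
  expect_false(meas$clipped)

  # identical translated shapes give ratio exactly 1
  blob <- random_blob(120, seed = 3)
  m <- matrix(0L, 80, 80)
  m[blob$pixels + 1L] <- 1L
  m[cbind(blob$pixels[, 1] + 1L, blob$pixels[, 2] + 41L)] <- 2L
  expect_identical(measure_frame(m)$ratio, 1)

  no_ao <- rect_mask(10, 10, 2:5, 2:5)
  err <- tryCatch(measure_frame(no_ao), caliper_error = function(e) e)
  expect_s3_class(err, "missing_vessel")
  expect_match(conditionMessage(err), "Ao")
})
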