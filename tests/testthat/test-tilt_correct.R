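test_that("tilt ROI cropping honours bounds and clips with a warning", {
  frame <- matrix(runif(960 * 720), 720, 960)
  sub <- extract_tilt_roi(frame)
  expect_equal(dim(sub), c(500, 800))
  expect_identical(extract_tilt_roi(frame, c(0, 0, 960, 720)), frame)
  expect_warning(big <- extract_tilt_roi(frame, c(900, 700, 200, 100)),
                 "clipping")
  expect_equal(dim(big), c(20, 60))
})

test_that("segment slopes follow the endpoint formula", {
  expect_equal(segment_slope(list(x1 = 0, y1 = 0, x2 = 10, y2 = 5)), 0.5)
  expect_equal(segment_slope(list(x1 = 3, y1 = 7, x2 = 13, y2 = 7)), 0)
  expect_true(is.na(segment_slope(list(x1 = 5, y1 = 0, x2 = 5, y2 = 9))))
})

test_that("trimmed mean removes one max and one min instance", {
  expect_equal(trimmed_mean_slope(c(0.1, 0.2, 0.3, 0.4, 0.9)), 0.3)
  expect_equal(trimmed_mean_slope(c(0.7, 0.7, 0.7)), 0.7)
  expect_warning(k <- trimmed_mean_slope(c(0.5, 0.7)), "plain mean")
  expect_equal(k, 0.6)
  expect_warning(k0 <- trimmed_mean_slope(numeric(0)), "no usable slopes")
  expect_equal(k0, 0)
})

test_that("trimmed mean is permutation-invariant and bounded", {
  set.seed(5)
  for (i in 1:20) {
    s <- rnorm(sample(3:30, 1))
    k <- trimmed_mean_slope(s)
    expect_equal(trimmed_mean_slope(sample(s)), k)
    expect_gte(k, min(s))
    expect_lte(k, max(s))
  }
})

test_that("slope-to-angle offers the geometric and the legacy formula", {
  expect_equal(slope_to_angle(0), 0)
  expect_equal(slope_to_angle(0, "legacy"), 0)
  expect_equal(slope_to_angle(1), pi / 4)
  # the two formulas diverge by almost two orders of magnitude at a 2-degree slope
  expect_equal(slope_to_angle(0.0349), 0.0348858, tolerance = 1e-5)
  expect_equal(slope_to_angle(0.0349, "legacy"), 0.00060911991, tolerance = 1e-6)
})

test_that("rotation matrix fixes the centre and matches direct rotation", {
  id <- rotation_matrix(0, 960, 720)
  expect_equal(id$A, matrix(c(1, 0, 0, 0, 1, 0), 2, byrow = TRUE))
  rs <- rotation_matrix(pi / 2, 960, 720)
  expect_equal(rs$alpha^2 + rs$beta^2, 1, tolerance = 1e-9)
  expect_equal(as.vector(rs$A %*% c(480, 360, 1)), c(480, 360),
               tolerance = 1e-6)
  # mapping of an arbitrary point: p -> c + R (p - c), y-down convention
  th <- 0.0349
  rs2 <- rotation_matrix(th, 960, 720)
  p <- c(0, 0)
  direct <- c(480, 360) + matrix(c(cos(th), sin(th), -sin(th), cos(th)),
                                 2, byrow = TRUE) %*% (p - c(480, 360))
  expect_equal(as.vector(rs2$A %*% c(p, 1)), as.vector(direct),
               tolerance = 1e-9)
})

test_that("rotation by an identity spec is exact and round-trips are lossless", {
  rt <- flat_tray()
  id <- rotation_matrix(0, 960, 720)
  expect_identical(rotate_image(rt$frame, id), rt$frame)
  th <- 2 * pi / 180
  fwd <- rotate_image(rt$frame, rotation_matrix(th, 960, 720))
  back <- rotate_image(fwd, rotation_matrix(-th, 960, 720))
  # interpolation loss only, measured on the 8-bit scale
  expect_lt(mean(abs(back - rt$frame)) * 255, 5)
})

test_that("tilt is recovered and removed on a synthetic tray", {
  sp <- tray_spec(tilt_deg = 2, rng_seed = 17)
  rt <- render_tray(sp)
  est <- estimate_tilt(rt$frame)
  expect_gte(est$n, 3)
  expect_lt(abs(est$theta_deg - 2), 0.2)
  corrected <- correct_tilt(rt$frame)
  residual <- estimate_tilt(corrected$frame)
  expect_lt(abs(residual$theta_deg), 0.2)
})
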