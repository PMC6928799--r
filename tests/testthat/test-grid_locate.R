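test_that("preprocessing binarises, removes speckle and keeps lines", {
  g <- matrix(0, 100, 100)
  set.seed(2)
  # 50 isolated bright pixels, no two adjacent
  spots <- cbind(rep(seq(3L, 93L, by = 10L), 5), rep(seq(5L, 85L, by = 20L), each = 10))
  g[spots] <- 0.8
  g[40:42, 5:95] <- 0.8   # 3-px-thick bar survives a 3x3 opening
  img <- array(rep(g, 3), dim = c(100, 100, 3))
  bin <- preprocess_grid(img)
  expect_equal(sum(bin[spots]), 0)
  expect_gte(mean(bin[41, 6:94]), 0.95)
  expect_true(all(preprocess_grid(matrix(0, 10, 10)) == 0))
})

test_that("preprocessed grid image covers the true gridline raster", {
  rt <- flat_tray()
  seg <- segment_classes(rt$frame)
  bin <- preprocess_grid(seg$grid)
  gm <- rt$truth$grid_mask
  # opening erodes line ends; interior coverage must stay high
  interior <- gm
  interior[c(1:30, 691:720), ] <- 0
  interior[, c(1:30, 931:960)] <- 0
  expect_gte(sum(bin * interior) / sum(interior), 0.95)
})

test_that("projection profiles sum binary pixels per row or column", {
  img <- matrix(0, 5, 5)
  img[3, ] <- 1   # all-ones row at 0-based index 2
  p <- projection_profile(img, "rows")
  expect_equal(p$index, 0:4)
  expect_equal(p$pixel_sum, c(0, 0, 5, 0, 0))
  set.seed(6)
  m <- matrix(rbinom(120, 1, 0.3), 10, 12)
  pr <- projection_profile(m, "rows")
  pc <- projection_profile(m, "columns")
  expect_equal(pr$pixel_sum, projection_profile(t(m), "columns")$pixel_sum)
  expect_equal(sum(pr$pixel_sum), sum(pc$pixel_sum))
  expect_equal(sum(pr$pixel_sum), sum(m))
})

test_that("gridline localisation finds per-block maxima with central ties", {
  prof <- data.frame(index = 0:119, pixel_sum = 0)
  prof$pixel_sum[c(11, 51, 91)] <- c(40, 55, 38)   # spikes at 10, 50, 90
  expect_equal(locate_gridlines(prof, 3), c(10, 50, 90))
  flat <- data.frame(index = 0:9, pixel_sum = rep(2, 10))
  expect_equal(locate_gridlines(flat, 2), c(2, 7))   # centre of each half
  expect_error(locate_gridlines(flat, 0), "n_groups")
  expect_error(locate_gridlines(flat[0, ], 2), "empty")
  expect_error(locate_gridlines(flat, 11), "shorter")
})

test_that("localisation matches the brute-force oracle on random profiles", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(20:150, 1)
    prof <- data.frame(index = 0:(n - 1),
                       pixel_sum = sample(0:12, n, replace = TRUE))
    g <- sample(1:8, 1)
    expect_identical(locate_gridlines(prof, g), oracle_locate(prof, g))
  }
})

test_that("gridlines of a flat tray are recovered to within 2 px", {
  rt <- flat_tray()
  bin <- preprocess_grid(segment_classes(rt$frame)$grid)
  rl <- locate_gridlines(projection_profile(bin, "rows"), 11)
  cl <- locate_gridlines(projection_profile(bin, "columns"), 14)
  expect_length(rl, 11)
  expect_length(cl, 14)
  expect_lte(max(abs(rl - rt$truth$row_lines)), 2)
  expect_lte(max(abs(cl - rt$truth$col_lines)), 2)
})

test_that("grid coordinates validate ordering and spacing regularity", {
  expect_error(grid_coordinates(c(5, 5, 10), c(0, 10)), "strictly increasing")
  expect_error(grid_coordinates(c(0, 10, 20, 60), c(0, 10, 20)),
               class = "traysow_unreadable")
  gc <- grid_coordinates(seq(0, 500, 50), seq(0, 780, 60))
  expect_s3_class(gc, "grid_coordinates")
})

test_that("ROI selection spans the first 11 x 14 gridlines", {
  gc <- grid_coordinates(seq(0, 500, 50), seq(0, 780, 60))
  roi <- select_roi(gc)
  expect_equal(unname(roi$rect), c(0, 0, 780, 500))
  expect_length(roi$row_lines, 11)
  short <- grid_coordinates(seq(0, 450, 50), seq(0, 780, 60))
  expect_error(select_roi(short), class = "traysow_unreadable")
})

test_that("the located ROI contains every ground-truth cell interior", {
  rt <- flat_tray()
  bin <- preprocess_grid(segment_classes(rt$frame)$grid)
  coords <- grid_coordinates(
    locate_gridlines(projection_profile(bin, "rows"), 11),
    locate_gridlines(projection_profile(bin, "columns"), 14))
  roi <- select_roi(coords)
  truth <- rt$truth
  # every seeded pixel lies inside the ROI rectangle
  seed_px <- which(truth$seed_mask == 1, arr.ind = TRUE)
  expect_true(all(seed_px[, 1] - 1 >= roi$rect["y0"] &
                  seed_px[, 1] - 1 < roi$rect["y1"]))
  expect_true(all(seed_px[, 2] - 1 >= roi$rect["x0"] &
                  seed_px[, 2] - 1 < roi$rect["x1"]))
})
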