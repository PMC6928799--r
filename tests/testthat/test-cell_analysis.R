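test_that("the ROI splits into half-open, tiling pieces", {
  bin <- matrix(rbinom(800 * 700, 1, 0.1), 700, 800)
  roi <- list(row_lines = seq(0, 500, 50), col_lines = seq(0, 780, 60))
  pieces <- split_into_pieces(bin, roi)
  expect_length(pieces, 130)
  expect_equal(dim(pieces[[1]]$mask), c(50, 60))
  # tiling conservation: piece pixels sum to the ROI pixels
  roi_sum <- sum(bin[1:500, 1:780])
  expect_equal(sum(vapply(pieces, function(p) sum(p$mask), numeric(1))),
               roi_sum)
  small <- split_into_pieces(bin, list(row_lines = c(0, 50, 100),
                                       col_lines = c(0, 60, 120)))
  expect_length(small, 4)
  expect_error(split_into_pieces(matrix(0, 10, 10), roi), "exceed")
})

test_that("the 30-px area filter removes impurities and keeps seeds", {
  blob30 <- matrix(0, 20, 20)
  blob30[8:12, 8:13] <- 1                  # 5 x 6 = 30 px
  expect_equal(nrow(find_and_filter_contours(blob30)), 1)
  blob29 <- blob30
  blob29[8, 8] <- 0                         # 29 px
  expect_equal(nrow(find_and_filter_contours(blob29)), 0)
  expect_equal(nrow(find_and_filter_contours(matrix(0, 20, 20))), 0)
})

test_that("empty cells are counted from contour-free pieces", {
  blob <- matrix(0, 20, 20); blob[5:12, 5:12] <- 1
  contours <- lapply(list(blob, matrix(0, 20, 20), blob, matrix(0, 20, 20)),
                     find_and_filter_contours)
  expect_equal(count_empty_cells(contours), 2)
  expect_equal(count_empty_cells(lapply(1:3, function(i)
    find_and_filter_contours(matrix(0, 5, 5)))), 3)
})

test_that("missing rate follows m / N and is scale-invariant", {
  expect_equal(round(missing_rate(10, 390), 2), 2.56)
  expect_equal(missing_rate(0, 130), 0)
  expect_equal(missing_rate(130, 130), 100)
  for (k in c(2, 3, 7)) {
    expect_equal(missing_rate(6 * k, 130 * k), missing_rate(6, 130))
  }
  expect_error(missing_rate(5, 0), "positive")
  expect_error(missing_rate(-1, 10), "lie in")
  expect_error(missing_rate(11, 10), "lie in")
})

test_that("shape factor is 1 for a circle and 4/pi for a square", {
  r <- 7.3
  expect_equal(shape_factor(2 * pi * r, pi * r^2), 1)
  s <- 11
  expect_equal(shape_factor(4 * s, s^2), 4 / pi)
  expect_error(shape_factor(10, 0), "positive")
})

test_that("measured features of a rasterized ellipse match analytic values", {
  a <- 16; b <- 8   # 2:1 aspect
  feats <- find_and_filter_contours(raster_ellipse(a, b))
  expect_equal(nrow(feats), 1)
  expect_equal(feats$area, pi * a * b, tolerance = 0.05)
  # Ramanujan perimeter approximation
  h <- (a - b)^2 / (a + b)^2
  C <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  expect_equal(feats$perimeter, C, tolerance = 0.1)
  F_analytic <- C^2 / (4 * pi * pi * a * b)
  expect_equal(feats$shape_factor, F_analytic, tolerance = 0.1)
})

test_that("discrete shape factors stay above the degenerate floor", {
  set.seed(21)
  for (i in 1:10) {
    a <- runif(1, 5, 18); b <- runif(1, 4, a)
    feats <- find_and_filter_contours(raster_ellipse(a, b))
    expect_gt(feats$shape_factor, 0.5)
  }
})

test_that("the activation is the odd bipolar sigmoid", {
  f <- traysow:::bp_activation
  expect_equal(f(0), 0)
  x <- seq(-6, 6, by = 0.7)
  expect_equal(f(x) + f(-x), rep(0, length(x)))
  expect_true(all(abs(f(x)) < 1))
  # matches the rational form (1 - e^-x) / (1 + e^-x)
  expect_equal(f(x), (1 - exp(-x)) / (1 + exp(-x)))
})

test_that("training is deterministic and serialization round-trips", {
  ds <- small_samples()
  c1 <- bp_train(ds, epochs = 200, rng_seed = 12)
  c2 <- bp_train(ds, epochs = 200, rng_seed = 12)
  expect_identical(c1$W1, c2$W1)
  expect_identical(c1$w2, c2$w2)
  path <- file.path(tempdir(), "counter.json")
  save_seed_counter(c1, path)
  c3 <- load_seed_counter(path)
  probe <- ds[seq(1, nrow(ds), by = 7), ]
  expect_equal(as.integer(bp_forward(probe, c3)),
               as.integer(bp_forward(probe, c1)), tolerance = 1e-12)
  expect_error(bp_train(ds[0, ], rng_seed = 1), "empty")
  expect_error(bp_train(ds[ds$label == 1, ], rng_seed = 1), "2 classes")
})

test_that("predictions are clamped to the 1..5 label range", {
  ctr <- small_counter()
  extreme <- data.frame(area = c(1e-3, 1e6), perimeter = c(1e-3, 1e5),
                        shape_factor = c(0.01, 50))
  p <- bp_forward(extreme, ctr)
  expect_true(all(p >= 1))
  expect_true(all(p <= 5))
  expect_type(attr(p, "overflow"), "logical")
})

test_that("single-seed contours are predicted as one seed", {
  ctr <- small_counter()
  ones <- small_samples()
  ones <- ones[ones$label == 1, ][1:40, ]
  p <- bp_forward(ones, ctr)
  expect_gte(mean(p == 1), 0.9)
})

test_that("seed totals sum per-contour predictions with a floor of one", {
  ctr <- small_counter()
  expect_equal(count_seeds(list(), ctr), 0L)
  blob <- matrix(0, 30, 30); blob[10:20, 10:22] <- 1
  contours <- lapply(1:4, function(i) find_and_filter_contours(blob))
  expect_gte(count_seeds(contours, ctr), 4)
})
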