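#' Fixed-threshold segmentation in the HSL colour model
#'
#' The grid and seed pixels of a pot-tray frame occupy nearly disjoint hue
#' bands, so both classes can be extracted with fixed thresholds on the H
#' channel alone. Channels follow the 8-bit machine-vision convention:
#' H on the half-degree scale in `[0, 180)`, S and L in `[0, 255]`.
#'
#' @param img RGB array `[y, x, 3]` with values in `[0, 1]`.
#' @return Array `[y, x, 3]` with channels H, S, L.
#' @export
#' @examples
#' px <- array(c(1, 0, 0), dim = c(1, 1, 3))
#' rgb_to_hsl(px)[1, 1, 1]  # pure red has hue 0
rgb_to_hsl <- function(img) {
  if (!is_rgb_array(img)) stop("rgb_to_hsl() expects a 3-channel array [y, x, 3]")
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  l <- (mx + mn) / 2
  c <- mx - mn
  s <- ifelse(c == 0, 0, c / (1 - abs(2 * l - 1)))
  # hue in degrees, piecewise on the dominant channel
  h <- r * 0
  im <- c > 0 & mx == r
  h[im] <- 60 * (((g - b)[im] / c[im]) %% 6)
  im <- c > 0 & mx == g & mx != r
  h[im] <- 60 * ((b - r)[im] / c[im] + 2)
  im <- c > 0 & mx == b & mx != r & mx != g
  h[im] <- 60 * ((r - g)[im] / c[im] + 4)
  out <- array(0, dim = dim(img))
  out[, , 1] <- (h / 2) %% 180
  out[, , 2] <- s * 255
  out[, , 3] <- l * 255
  out
}

# Inverse conversion, used by the synthetic renderer. Inputs on the same
# scales as rgb_to_hsl() output; returns RGB in [0, 1].
hsl_to_rgb <- function(h, s, l) {
  hd <- (h * 2) %% 360
  s1 <- s / 255
  l1 <- l / 255
  c <- (1 - abs(2 * l1 - 1)) * s1
  x <- c * (1 - abs((hd / 60) %% 2 - 1))
  m <- l1 - c / 2
  sector <- floor(hd / 60) %% 6
  r <- ifelse(sector == 0 | sector == 5, c, ifelse(sector == 1 | sector == 4, x, 0))
  g <- ifelse(sector == 1 | sector == 2, c, ifelse(sector == 0 | sector == 3, x, 0))
  b <- ifelse(sector == 3 | sector == 4, c, ifelse(sector == 2 | sector == 5, x, 0))
  cbind(r + m, g + m, b + m)
}

#' Default hue thresholds for grid and seed pixels
#'
#' Half-degree hue bands within which grid and seed pixels fall under the
#' cabinet's uniform illumination; soil hues lie between the two bands and
#' are treated as background.
#'
#' @param grid,seed Length-2 numeric vectors `c(H_min, H_max)`.
#' @return A list with elements `grid` and `seed`.
#' @export
hsl_thresholds <- function(grid = c(3, 30), seed = c(70, 168)) {
  for (rng in list(grid, seed)) {
    stopifnot(length(rng) == 2L, rng[1] >= 0, rng[1] < rng[2], rng[2] < 181)
  }
  list(grid = as.numeric(grid), seed = as.numeric(seed))
}

#' Build a binary class mask from the hue channel
#'
#' A pixel belongs to the class iff its hue lies strictly between the
#' thresholds: `H_min < H < H_max`. The S and L channels are ignored.
#'
#' @param hsl_image Array from [rgb_to_hsl()].
#' @param H_min,H_max Hue thresholds on the half-degree scale.
#' @return Binary matrix (0/1) with the image's spatial dimensions.
#' @export
build_mask <- function(hsl_image, H_min, H_max) {
  stopifnot(is_rgb_array(hsl_image), H_min >= 0, H_min < H_max, H_max < 181)
  h <- hsl_image[, , 1]
  (h > H_min & h < H_max) * 1
}

#' Apply a binary mask to an image
#'
#' Keeps pixels where the mask is 1 and zeroes the rest (per-channel AND
#' with the mask).
#'
#' @param image Matrix or RGB array.
#' @param mask Binary matrix of matching spatial dimensions.
#' @return Image of the same shape as `image`.
#' @export
apply_mask <- function(image, mask) {
  sp <- if (is.matrix(image)) dim(image) else dim(image)[1:2]
  if (!identical(sp, dim(mask))) stop("mask dimensions do not match image")
  if (is.matrix(image)) return(image * mask)
  out <- image
  for (k in 1:3) out[, , k] <- image[, , k] * mask
  out
}

#' Extract grid and seed images by fixed hue thresholds
#'
#' Converts a corrected frame to HSL, builds one mask per class and applies
#' each mask to the frame.
#'
#' @param frame RGB array `[y, x, 3]`, already tilt-corrected.
#' @param thresholds A list from [hsl_thresholds()].
#' @return List with `grid`, `seed` (masked RGB arrays) and the binary
#'   `grid_mask`, `seed_mask` matrices.
#' @export
segment_classes <- function(frame, thresholds = hsl_thresholds()) {
  hsl <- rgb_to_hsl(frame)
  gm <- build_mask(hsl, thresholds$grid[1], thresholds$grid[2])
  sm <- build_mask(hsl, thresholds$seed[1], thresholds$seed[2])
  list(grid = apply_mask(frame, gm), seed = apply_mask(frame, sm),
       grid_mask = gm, seed_mask = sm)
}

#' Pixel-sum segmentation accuracy
#'
#' Compares the pixel sums of a predicted and a reference binary image as
#' `100 * min / max`, a symmetric score that is 100 when the sums agree.
#' Two empty images agree perfectly by convention.
#'
#' @param pred_binary,ref_binary Binary matrices of equal dimensions.
#' @return Accuracy in percent.
#' @export
segmentation_accuracy <- function(pred_binary, ref_binary) {
  if (!identical(dim(pred_binary), dim(ref_binary))) {
    stop("binary images must have identical dimensions")
  }
  sp <- sum(pred_binary != 0)
  sr <- sum(ref_binary != 0)
  if (sp == 0 && sr == 0) return(100)
  100 * min(sp, sr) / max(sp, sr)
}
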