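#' The 3-6-1 seed-counting network
#'
#' A small feed-forward network maps the (area, perimeter, shape factor)
#' of one contour to the number of seeds merged in that contour. Three
#' input nodes, six hidden nodes with the bipolar sigmoid activation
#' `f(x) = (1 - exp(-x)) / (1 + exp(-x))` and one linear output node.
#' Inputs and the target are z-score standardised; training is full-batch
#' gradient back-propagation on squared error with momentum, deterministic
#' for a fixed seed.
#'
#' @name seed_counter
NULL

# Bipolar sigmoid (algebraically tanh(x/2)); odd, f(0) = 0, |f| < 1.
bp_activation <- function(x) tanh(x / 2)

#' Train the seed-counting network
#'
#' @param dataset Data frame with `area`, `perimeter`, `shape_factor` and
#'   integer `label` (seeds per contour; the top class pools "more than
#'   four").
#' @param hidden Hidden-layer width.
#' @param lr Learning rate.
#' @param epochs Full-batch gradient steps.
#' @param momentum Momentum coefficient.
#' @param rng_seed Seed for the weight initialisation.
#' @return An object of class `seed_counter`.
#' @export
bp_train <- function(dataset, hidden = 6L, lr = 0.01, epochs = 2000L,
                     momentum = 0.9, rng_seed = 1L) {
  need <- c("area", "perimeter", "shape_factor", "label")
  if (!nrow(dataset)) stop("empty training dataset")
  stopifnot(all(need %in% names(dataset)))
  if (length(unique(dataset$label)) < 2) stop("need at least 2 classes to train")
  X <- as.matrix(dataset[, c("area", "perimeter", "shape_factor")])
  y <- as.numeric(dataset$label)
  x_center <- colMeans(X)
  x_scale <- apply(X, 2, stats::sd)
  x_scale[x_scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  y_center <- mean(y)
  y_scale <- stats::sd(y)
  if (y_scale == 0) y_scale <- 1
  ys <- (y - y_center) / y_scale
  n <- nrow(Xs)
  with_seed(rng_seed, {
    W1 <- matrix(runif(3 * hidden, -0.5, 0.5), 3, hidden)
    b1 <- runif(hidden, -0.5, 0.5)
    w2 <- matrix(runif(hidden, -0.5, 0.5), hidden, 1)
    b2 <- runif(1, -0.5, 0.5)
    vW1 <- W1 * 0; vb1 <- b1 * 0; vw2 <- w2 * 0; vb2 <- 0
    loss <- NA_real_
    for (e in seq_len(epochs)) {
      Z <- sweep(Xs %*% W1, 2, b1, "+")
      Hh <- bp_activation(Z)
      yhat <- drop(Hh %*% w2) + b2
      err <- yhat - ys
      loss <- mean(err^2) / 2
      d_out <- err / n
      g_w2 <- crossprod(Hh, d_out)
      g_b2 <- sum(d_out)
      d_hid <- (matrix(d_out, ncol = 1) %*% t(w2)) * (1 - Hh^2) / 2
      g_W1 <- crossprod(Xs, d_hid)
      g_b1 <- colSums(d_hid)
      vW1 <- momentum * vW1 - lr * g_W1; W1 <- W1 + vW1
      vb1 <- momentum * vb1 - lr * g_b1; b1 <- b1 + vb1
      vw2 <- momentum * vw2 - lr * g_w2; w2 <- w2 + vw2
      vb2 <- momentum * vb2 - lr * g_b2; b2 <- b2 + vb2
    }
    structure(list(arch = c(3L, hidden, 1L), W1 = W1, b1 = b1,
                   w2 = drop(w2), b2 = b2,
                   x_center = x_center, x_scale = x_scale,
                   y_center = y_center, y_scale = y_scale,
                   label_max = max(dataset$label),
                   final_loss = loss,
                   hyperparams = list(lr = lr, epochs = epochs,
                                      momentum = momentum,
                                      rng_seed = rng_seed),
                   version = "traysow-seed-counter-1"),
              class = "seed_counter")
  })
}

#' Predict seeds per contour
#'
#' Standardises the features, propagates them through the network and
#' rounds the de-standardised output to the nearest integer, clamped to
#' at least 1 (a surviving contour holds at least one seed) and at most
#' the top training class. Predictions hitting the ceiling carry an
#' `overflow` attribute flag, since the regression head cannot distinguish
#' counts above its label ceiling.
#'
#' @param features Data frame (or matrix) with columns `area`,
#'   `perimeter`, `shape_factor`; one row per contour.
#' @param counter A trained `seed_counter`.
#' @return Integer vector of per-contour seed counts with attribute
#'   `overflow` (logical vector).
#' @export
bp_forward <- function(features, counter) {
  if (!inherits(counter, "seed_counter")) stop("counter is not a trained seed_counter")
  X <- if (is.matrix(features)) {
    features[, 1:3, drop = FALSE]
  } else {
    as.matrix(features[, c("area", "perimeter", "shape_factor")])
  }
  Xs <- sweep(sweep(X, 2, counter$x_center), 2, counter$x_scale, "/")
  Hh <- bp_activation(sweep(Xs %*% counter$W1, 2, counter$b1, "+"))
  raw <- (drop(Hh %*% counter$w2) + counter$b2) * counter$y_scale + counter$y_center
  pred <- pmax(1L, round(raw))
  over <- pred >= counter$label_max
  pred <- pmin(pred, counter$label_max)
  structure(as.integer(pred), overflow = over)
}

#' Serialize and restore a trained counter
#'
#' The model is written as versioned JSON (architecture, weights,
#' standardisation constants) and reloads losslessly.
#'
#' @param counter A trained `seed_counter`.
#' @param path Output JSON path.
#' @return `load_seed_counter()` returns the restored `seed_counter`.
#' @export
save_seed_counter <- function(counter, path) {
  stopifnot(inherits(counter, "seed_counter"))
  obj <- unclass(counter)
  obj$W1 <- as.vector(obj$W1)   # stored column-major with the arch alongside
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_seed_counter
#' @export
load_seed_counter <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$version, "traysow-seed-counter-1")) {
    stop("unrecognised seed-counter model version")
  }
  obj$arch <- as.integer(obj$arch)
  obj$W1 <- matrix(obj$W1, obj$arch[1], obj$arch[2])
  obj$x_center <- unlist(obj$x_center)
  obj$x_scale <- unlist(obj$x_scale)
  structure(obj, class = "seed_counter")
}
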