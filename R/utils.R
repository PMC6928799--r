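# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

is_rgb_array <- function(x) is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L

# Rec.601 luminance; accepts an RGB array or passes a matrix through.
to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  if (!is_rgb_array(img)) stop("expected an RGB array [y, x, 3] or a matrix")
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Connected-component labelling with 8-connectivity: EBImage::bwlabel is
# 4-connected, so labels touching only diagonally are merged afterwards.
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n < 2L) return(lab)
  parent <- seq_len(n)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union2 <- function(a, b) {
    ra <- find_root(a); rb <- find_root(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]          # down-right diagonal
  idx <- which(a > 0 & b > 0 & a != b)
  if (length(idx)) mapply(union2, a[idx], b[idx])
  a <- lab[-1, -nc]; b <- lab[-nr, -1]          # up-right diagonal
  idx <- which(a > 0 & b > 0 & a != b)
  if (length(idx)) mapply(union2, a[idx], b[idx])
  roots <- vapply(seq_len(n), find_root, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

round2 <- function(x) round(x, 2)
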