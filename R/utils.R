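# Low-level numeric helpers shared across modules. Images are numeric
# matrices indexed [row = y + 1, col = x + 1]; coordinates throughout the
# package are 0-based, x = column, y = row, pixel-center convention.

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) pmax(x, 0)

#' Row-wise softmax of a matrix
#' @noRd
softmax_rows <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

stopifnot_odd_window <- function(window, h, w) {
  if (length(window) != 1L || window < 3L || window %% 2L == 0L) {
    stop("`window` must be an odd integer >= 3", call. = FALSE)
  }
  if (window > h || window > w) {
    stop("`window` (", window, ") exceeds image size ", h, "x", w, call. = FALSE)
  }
  invisible(as.integer(window))
}

#' Reflection-pad a matrix by `k` pixels on every side
#'
#' Uses half-sample symmetric reflection (edge row/col repeated first in the
#' mirror), the convention of most image toolkits.
#' @noRd
reflect_pad <- function(m, k) {
  if (k == 0L) return(m)
  h <- nrow(m); w <- ncol(m)
  ridx <- c(rev(seq_len(min(k, h))), seq_len(h), h + 1L - rev(seq_len(min(k, h))))
  # for k > dim fall back to clamping (never hit with validated windows)
  ridx <- pmin(pmax(ridx, 1L), h)
  cidx <- c(rev(seq_len(min(k, w))), seq_len(w), w + 1L - rev(seq_len(min(k, w))))
  cidx <- pmin(pmax(cidx, 1L), w)
  m[ridx, cidx, drop = FALSE]
}

#' Separable cross-correlation with reflection padding
#'
#' `kx` runs over column offsets, `ky` over row offsets; both length-w vectors
#' centered at (w+1)/2. Output has the input's shape.
#' @noRd
corr_sep <- function(m, ky, kx) {
  k <- (length(ky) - 1L) %/% 2L
  p <- reflect_pad(m, k)
  h <- nrow(m); w <- ncol(m)
  # rows pass
  acc <- matrix(0, h, ncol(p))
  for (i in seq_along(ky)) {
    if (ky[i] != 0) acc <- acc + ky[i] * p[i:(i + h - 1L), , drop = FALSE]
  }
  out <- matrix(0, h, w)
  for (j in seq_along(kx)) {
    if (kx[j] != 0) out <- out + kx[j] * acc[, j:(j + w - 1L), drop = FALSE]
  }
  out
}

#' Windowed box sum with reflection padding (via separable correlation)
#' @noRd
box_sum <- function(m, window) {
  ones <- rep(1, window)
  corr_sep(m, ones, ones)
}

#' Bilinear sample of a single-channel grid at fractional 0-based (x, y)
#'
#' Out-of-bounds coordinates clamp to the border.
#' @noRd
bilinear_sample <- function(m, x, y) {
  h <- nrow(m); w <- ncol(m)
  x <- pmin(pmax(x, 0), w - 1)
  y <- pmin(pmax(y, 0), h - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x1 + 1)
  i10 <- cbind(y1 + 1, x0 + 1); i11 <- cbind(y1 + 1, x1 + 1)
  (1 - fy) * ((1 - fx) * m[i00] + fx * m[i01]) +
    fy * ((1 - fx) * m[i10] + fx * m[i11])
}

#' Bilinear sample of an N x h token grid (rows = row-major tokens)
#'
#' `feat` holds tokens of an H x W grid flattened row-major (x fastest); each
#' row is an h-vector. Returns a length(x) x h matrix.
#' @noRd
bilinear_sample_tokens <- function(feat, H, W, x, y) {
  x <- pmin(pmax(x, 0), W - 1)
  y <- pmin(pmax(y, 0), H - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, W - 1); y1 <- pmin(y0 + 1, H - 1)
  fx <- x - x0; fy <- y - y0
  idx <- function(xx, yy) yy * W + xx + 1
  (1 - fy) * (1 - fx) * feat[idx(x0, y0), , drop = FALSE] +
    (1 - fy) * fx       * feat[idx(x1, y0), , drop = FALSE] +
    fy       * (1 - fx) * feat[idx(x0, y1), , drop = FALSE] +
    fy       * fx       * feat[idx(x1, y1), , drop = FALSE]
}

#' Layer normalization over rows of a token matrix
#' @noRd
layer_norm <- function(m, eps = 1e-6) {
  mu <- rowMeans(m)
  v <- rowMeans((m - mu)^2)
  (m - mu) / sqrt(v + eps)
}

#' Gaussian random matrix scaled for fan-in
#' @noRd
rand_mat <- function(nr, nc, scale = NULL) {
  if (is.null(scale)) scale <- 1 / sqrt(nr)
  matrix(stats::rnorm(nr * nc, sd = scale), nr, nc)
}

#' Run `expr` under a temporary RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
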