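# Motion decoupling: local polynomial (quadratic) intensity models per frame,
# closed-form displacement between consecutive fits, polar transform, adaptive
# dual thresholds and trinary filtering into sparse motion features.
#
# Frames are numeric matrices in [0, 1]; all windowed operators use reflection
# padding; coordinates are 0-based (x = column, y = row).

# quadratic basis over a window: model(u,v) = c + bx*u + by*v
#                                 + 0.5*Axx*u^2 + 0.5*Ayy*v^2 + Axy*u*v
# internal coefficient order: (c, bx, by, qxx, qyy, qxy) with
# Axx = 2*qxx, Ayy = 2*qyy, Axy = qxy.

poly_gaussian_weights <- function(window) {
  # OpenCV-style width-to-sigma rule; any smooth applicability works, the
  # fit is exact for quadratic inputs regardless.
  sigma <- 0.3 * ((window - 1) * 0.5 - 1) + 0.8
  k <- (window - 1L) %/% 2L
  u <- seq(-k, k)
  w <- exp(-u^2 / (2 * sigma^2))
  w / sum(w)
}

#' Fit a local quadratic intensity model at every pixel
#'
#' Approximates the image in a `window` x `window` neighborhood of each pixel
#' by the quadratic form `0.5 * p' A p + b' p + c` (p = offset from the window
#' center), by Gaussian-weighted least squares with optional ridge penalties
#' `lambda * alpha` on the curvature matrix `A` (Frobenius norm) and
#' `lambda * beta` on the gradient `b`. Borders are handled by reflection
#' padding.
#'
#' @param frame numeric matrix of finite intensities.
#' @param window odd window width, at least 3, no larger than the image.
#' @param alpha,beta,lambda penalty weights; the defaults give the plain
#'   unpenalized fit.
#' @return an object of class `poly_fit`: list with per-pixel matrices
#'   `axx`, `ayy`, `axy` (entries of the symmetric curvature matrix `A`),
#'   `bx`, `by` and `c`, all the shape of `frame`.
#' @export
fit_polynomial <- function(frame, window = 5L, alpha = 0, beta = 0, lambda = 1) {
  if (!is.matrix(frame) || !all(is.finite(frame))) {
    stop("`frame` must be a finite numeric matrix", call. = FALSE)
  }
  window <- stopifnot_odd_window(window, nrow(frame), ncol(frame))
  k <- (window - 1L) %/% 2L
  u <- seq(-k, k)
  w1 <- poly_gaussian_weights(window)

  # normal-equation matrix G = sum w * g g' is the same at every pixel
  W <- outer(w1, w1)                       # [v, u]
  U <- matrix(u, window, window, byrow = TRUE)
  V <- matrix(u, window, window)
  basis <- list(1 + 0 * U, U, V, U^2, V^2, U * V)
  G <- matrix(0, 6, 6)
  for (i in 1:6) for (j in i:6) {
    G[i, j] <- G[j, i] <- sum(W * basis[[i]] * basis[[j]])
  }
  # || A ||_F^2 = 4 qxx^2 + 4 qyy^2 + 2 qxy^2 ; || b ||^2 = bx^2 + by^2
  reg <- lambda * diag(c(0, beta, beta, 4 * alpha, 4 * alpha, 2 * alpha))
  Ginv <- solve(G + reg)

  # per-pixel right-hand sides: separable correlations with w * monomial
  ky0 <- w1; ky1 <- w1 * u; ky2 <- w1 * u^2
  rhs <- rbind(
    as.vector(corr_sep(frame, ky0, ky0)),   # 1
    as.vector(corr_sep(frame, ky0, ky1)),   # u  (x)
    as.vector(corr_sep(frame, ky1, ky0)),   # v  (y)
    as.vector(corr_sep(frame, ky0, ky2)),   # u^2
    as.vector(corr_sep(frame, ky2, ky0)),   # v^2
    as.vector(corr_sep(frame, ky1, ky1))    # uv
  )
  q <- Ginv %*% rhs
  shape <- dim(frame)
  out <- list(
    c   = matrix(q[1, ], shape[1], shape[2]),
    bx  = matrix(q[2, ], shape[1], shape[2]),
    by  = matrix(q[3, ], shape[1], shape[2]),
    axx = matrix(2 * q[4, ], shape[1], shape[2]),
    ayy = matrix(2 * q[5, ], shape[1], shape[2]),
    axy = matrix(q[6, ], shape[1], shape[2]),
    window = window
  )
  class(out) <- "poly_fit"
  out
}

sample_fit <- function(fit, x, y, shape) {
  lapply(fit[c("axx", "ayy", "axy", "bx", "by")], function(m) {
    matrix(bilinear_sample(m, as.vector(x), as.vector(y)), shape[1], shape[2])
  })
}

#' Estimate per-pixel displacement between two frames
#'
#' Dual polynomial expansion: both frames are fitted with [fit_polynomial],
#' and the displacement at each pixel is recovered from the averaged curvature
#' and the gradient difference, aggregated over the local window and solved
#' with a ridge-stabilized 2x2 inversion. A small number of fixed-point
#' refinement passes re-samples the second frame's fit at the displaced
#' position.
#'
#' @param frame_t,frame_next same-shape numeric matrices.
#' @param window odd window width (fit and aggregation), default 5.
#' @param alpha,beta,lambda penalties on curvature/gradient of the fits.
#' @param ridge stabilizer added to the normal equations.
#' @param iters refinement passes (>= 1).
#' @return object of class `displacement_field`: list with matrices `dx`, `dy`.
#' @export
estimate_displacement <- function(frame_t, frame_next, window = 5L,
                                  alpha = 0.1, beta = 0.01, lambda = 1,
                                  ridge = 1e-4, iters = 5L) {
  if (!identical(dim(frame_t), dim(frame_next))) {
    stop("frames must share shape", call. = FALSE)
  }
  h <- nrow(frame_t); w <- ncol(frame_t)
  f1 <- fit_polynomial(frame_t, window, alpha, beta, lambda)
  f2 <- fit_polynomial(frame_next, window, alpha, beta, lambda)

  xg <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
  yg <- matrix(seq_len(h) - 1, h, w)
  dx <- matrix(0, h, w); dy <- matrix(0, h, w)

  for (it in seq_len(max(1L, iters))) {
    if (it == 1L) {
      s2 <- f2[c("axx", "ayy", "axy", "bx", "by")]
    } else {
      s2 <- sample_fit(f2, xg + dx, yg + dy, c(h, w))
    }
    a11 <- (f1$axx + s2$axx) / 2
    a22 <- (f1$ayy + s2$ayy) / 2
    a12 <- (f1$axy + s2$axy) / 2
    db_x <- -0.5 * (s2$bx - f1$bx) + a11 * dx + a12 * dy
    db_y <- -0.5 * (s2$by - f1$by) + a12 * dx + a22 * dy
    # windowed normal equations: M = sum w A'A, v = sum w A'db
    m11 <- box_sum(a11 * a11 + a12 * a12, window)
    m12 <- box_sum(a11 * a12 + a12 * a22, window)
    m22 <- box_sum(a12 * a12 + a22 * a22, window)
    v1 <- box_sum(a11 * db_x + a12 * db_y, window)
    v2 <- box_sum(a12 * db_x + a22 * db_y, window)
    m11 <- m11 + ridge; m22 <- m22 + ridge
    det <- m11 * m22 - m12 * m12
    ok <- is.finite(det) & det > 1e-12
    dx <- ifelse(ok, (m22 * v1 - m12 * v2) / det, 0)
    dy <- ifelse(ok, (m11 * v2 - m12 * v1) / det, 0)
    dx[!is.finite(dx)] <- 0
    dy[!is.finite(dy)] <- 0
  }
  structure(list(dx = dx, dy = dy), class = "displacement_field")
}

#' Polar transform of a displacement field
#'
#' `rho = sqrt(dx^2 + dy^2)`, `theta = atan2(dy, dx)`; `theta` is defined as 0
#' where `rho` is exactly 0.
#' @param field a `displacement_field` (or list with `dx`, `dy`).
#' @return object of class `polar_motion`: list with matrices `rho`, `theta`.
#' @export
to_polar <- function(field) {
  rho <- sqrt(field$dx^2 + field$dy^2)
  theta <- atan2(field$dy, field$dx)
  theta[rho == 0] <- 0
  structure(list(rho = rho, theta = theta), class = "polar_motion")
}

#' Windowed mean and standard deviation of the motion magnitude
#'
#' Population standard deviation over a sliding `stat_window` square with
#' reflection padding.
#' @param polar a `polar_motion`.
#' @param stat_window odd window width, default 31 (must comfortably
#'   exceed an agent's motion footprint so the local statistics describe the
#'   background).
#' @return list with matrices `mu`, `sigma`.
#' @export
local_statistics <- function(polar, stat_window = 31L) {
  rho <- polar$rho
  stat_window <- stopifnot_odd_window(stat_window, nrow(rho), ncol(rho))
  n <- stat_window^2
  mu <- box_sum(rho, stat_window) / n
  ex2 <- box_sum(rho^2, stat_window) / n
  sigma <- sqrt(pmax(ex2 - mu^2, 0))
  list(mu = mu, sigma = sigma)
}

#' Adaptive low/high motion thresholds
#'
#' `tau_low = mu + k1 * sigma`, `tau_high = mu + k2 * sigma` elementwise.
#' @param maps list with `mu`, `sigma` (from [local_statistics]).
#' @param k1,k2 threshold multipliers, `k2 >= k1`; defaults 1.0 and 2.5.
#' @return `maps` with `tau_low`, `tau_high` added.
#' @export
adaptive_thresholds <- function(maps, k1 = 1.0, k2 = 2.5) {
  if (k2 < k1) stop("k2 must be >= k1", call. = FALSE)
  maps$tau_low <- maps$mu + k1 * maps$sigma
  maps$tau_high <- maps$mu + k2 * maps$sigma
  maps
}

#' Trinary motion classification
#'
#' Label 0 (static) where `rho < tau_low`, 1 (uncertain) where
#' `tau_low <= rho <= tau_high`, 2 (confident) where `rho > tau_high`.
#' Pixels with `rho < min_rho` are always static, which keeps an all-static
#' frame (where `mu = sigma = 0` makes both thresholds 0) from being flagged
#' as uncertain motion everywhere.
#' @param polar a `polar_motion`.
#' @param maps threshold maps with `tau_low`, `tau_high` filled.
#' @param min_rho strict magnitude floor, default 1e-6.
#' @return integer matrix of labels in \{0, 1, 2\}.
#' @export
classify_motion <- function(polar, maps, min_rho = 1e-6) {
  rho <- polar$rho
  lab <- matrix(0L, nrow(rho), ncol(rho))
  lab[rho >= maps$tau_low & rho <= maps$tau_high] <- 1L
  lab[rho > maps$tau_high] <- 2L
  lab[rho < min_rho] <- 0L
  lab
}

#' Extract sparse motion features from a mask
#'
#' Keeps exactly the pixels labeled 1 or 2, each as (x, y, rho, theta).
#' @param polar a `polar_motion`.
#' @param mask label matrix from [classify_motion].
#' @return data.frame with columns `x`, `y` (0-based), `rho`, `theta`, `label`.
#' @export
sparse_features <- function(polar, mask) {
  if (!identical(dim(polar$rho), dim(mask))) {
    stop("mask and polar field shapes differ", call. = FALSE)
  }
  idx <- which(mask > 0L)
  h <- nrow(mask)
  rows <- (idx - 1L) %% h          # 0-based y
  cols <- (idx - 1L) %/% h         # 0-based x
  data.frame(
    x = cols, y = rows,
    rho = polar$rho[idx], theta = polar$theta[idx],
    label = as.integer(mask[idx])
  )
}

#' Rasterize sparse motion features to a dense 2-channel image
#'
#' Channel 1 carries `rho`, channel 2 `theta`; pixels without a feature are 0.
#' This dense (rho, theta) raster is the input of the motion-stream backbone.
#' @param features data.frame from [sparse_features].
#' @param shape integer (height, width).
#' @return array of dim `c(shape, 2)`.
#' @export
rasterize_motion <- function(features, shape) {
  h <- shape[1]; w <- shape[2]
  out <- array(0, dim = c(h, w, 2))
  if (nrow(features)) {
    if (any(features$x < 0 | features$x >= w | features$y < 0 | features$y >= h)) {
      stop("feature coordinates out of bounds", call. = FALSE)
    }
    i <- cbind(features$y + 1L, features$x + 1L)
    out[cbind(i, 1L)] <- features$rho
    out[cbind(i, 2L)] <- features$theta
  }
  out
}

#' Full motion-decoupling pipeline for a frame pair
#'
#' Runs displacement estimation, polar transform, adaptive thresholding,
#' trinary classification and sparsification in one call.
#' @param frame_t,frame_next same-shape frames.
#' @param cfg motion config sub-list (see [default_config()]`$motion`).
#' @return list with `field`, `polar`, `maps`, `mask`, `features`, `raster`.
#' @export
motion_features <- function(frame_t, frame_next, cfg = default_config()$motion) {
  field <- estimate_displacement(frame_t, frame_next,
    window = cfg$window, alpha = cfg$alpha, beta = cfg$beta,
    lambda = cfg$lambda, ridge = cfg$ridge, iters = cfg$iters)
  polar <- to_polar(field)
  maps <- adaptive_thresholds(local_statistics(polar, cfg$stat_window),
                              cfg$k1, cfg$k2)
  mask <- classify_motion(polar, maps, cfg$min_rho)
  feats <- sparse_features(polar, mask)
  list(field = field, polar = polar, maps = maps, mask = mask,
       features = feats, raster = rasterize_motion(feats, dim(frame_t)))
}
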