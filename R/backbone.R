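# Dual-stream multi-scale backbone. Each modality (appearance image, dense
# polar-motion raster) passes through four hierarchical stages at cumulative
# downsampling ratios 4, 8, 16, 32: overlapping patch embedding (3x3 strided
# conv) followed by transformer blocks with spatial-reduction attention.
# The profile (depths/widths) is a config, defaulting to a tiny randomly
# initialized instance so the full pipeline runs on a CPU in seconds; no
# pretrained weights are used or supported.

STAGE_RATIOS <- c(4L, 8L, 16L, 32L)
STAGE_STRIDES <- c(4L, 2L, 2L, 2L)
STAGE_SR <- c(4L, 2L, 1L, 1L)     # spatial-reduction factor for K/V tokens

#' Initialize backbone weights
#'
#' @param in_channels input channel count (1/3 appearance, 2 motion raster).
#' @param cfg model config sub-list (`depths`, `widths`).
#' @return parameter list, one entry per stage.
#' @export
init_backbone <- function(in_channels, cfg = default_config()$model) {
  widths <- as.integer(cfg$widths)
  depths <- as.integer(cfg$depths)
  stopifnot(length(widths) == 4L, length(depths) == 4L)
  stages <- vector("list", 4L)
  cin <- in_channels
  for (s in 1:4) {
    cw <- widths[s]
    blocks <- lapply(seq_len(depths[s]), function(i) {
      list(
        q = linear_init(cw, cw), k = linear_init(cw, cw),
        v = linear_init(cw, cw), o = linear_init(cw, cw),
        m1 = linear_init(cw, 2L * cw), m2 = linear_init(2L * cw, cw)
      )
    })
    stages[[s]] <- list(embed = conv_init(3L, 3L, cin, cw), blocks = blocks,
                        width = cw)
    cin <- cw
  }
  structure(list(stages = stages, widths = widths, depths = depths,
                 in_channels = in_channels), class = "backbone_params")
}

# average-pool an [H, W, C] map by integer factor f (ceil geometry)
pool_map <- function(x, f) {
  if (f <= 1L) return(x)
  h <- dim(x)[1]; w <- dim(x)[2]; C <- dim(x)[3]
  ho <- ceiling(h / f); wo <- ceiling(w / f)
  out <- array(0, dim = c(ho, wo, C))
  for (i in seq_len(ho)) for (j in seq_len(wo)) {
    ys <- ((i - 1L) * f + 1L):min(i * f, h)
    xs <- ((j - 1L) * f + 1L):min(j * f, w)
    out[i, j, ] <- apply(x[ys, xs, , drop = FALSE], 3L, mean)
  }
  out
}

sr_attention_block <- function(x, H, W, blk, sr) {
  # x: N x C row-major tokens
  C <- ncol(x)
  xn <- layer_norm(x)
  if (sr > 1L) {
    xm <- array(0, dim = c(H, W, C))
    for (ci in seq_len(C)) xm[, , ci] <- matrix(xn[, ci], H, W, byrow = TRUE)
    pm <- pool_map(xm, sr)
    kv <- matrix(0, dim(pm)[1] * dim(pm)[2], C)
    for (ci in seq_len(C)) kv[, ci] <- as.vector(t(pm[, , ci]))
  } else kv <- xn
  q <- linear_fwd(xn, blk$q); k <- linear_fwd(kv, blk$k); v <- linear_fwd(kv, blk$v)
  att <- softmax_rows(q %*% t(k) / sqrt(C)) %*% v
  x <- x + linear_fwd(att, blk$o)
  xn <- layer_norm(x)
  x + linear_fwd(relu(linear_fwd(xn, blk$m1)), blk$m2)
}

#' Extract the 4-stage feature pyramid of one input
#'
#' @param image matrix (grayscale) or array [H, W, C]; e.g. a frame or the
#'   2-channel polar-motion raster from [rasterize_motion()].
#' @param params from [init_backbone()].
#' @param modality `"appearance"` or `"motion"` tag carried on the result.
#' @return object of class `feature_pyramid`: list of 4 stages, each with
#'   `feat` (N x C row-major token matrix), `H`, `W`, `C`, `ratio`.
#' @export
extract_pyramid <- function(image, params, modality = "appearance") {
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1L))
  if (length(image) == 0L) stop("empty image", call. = FALSE)
  if (dim(image)[3] != params$in_channels) {
    stop("input has ", dim(image)[3], " channels, backbone expects ",
         params$in_channels, call. = FALSE)
  }
  x <- image
  stages <- vector("list", 4L)
  for (s in 1:4) {
    ps <- params$stages[[s]]
    x <- conv2d(x, ps$embed$W, ps$embed$b, stride = STAGE_STRIDES[s])
    H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
    tok <- matrix(0, H * W, C)
    for (ci in seq_len(C)) tok[, ci] <- as.vector(t(x[, , ci]))
    for (blk in ps$blocks) tok <- sr_attention_block(tok, H, W, blk, STAGE_SR[s])
    for (ci in seq_len(C)) x[, , ci] <- matrix(tok[, ci], H, W, byrow = TRUE)
    stages[[s]] <- list(feat = tok, H = H, W = W, C = C, ratio = STAGE_RATIOS[s])
  }
  structure(list(stages = stages, modality = modality), class = "feature_pyramid")
}

#' Multi-band sinusoidal positional encoding (pre-projection)
#'
#' For normalized coordinates `c` in each axis and band `l = 0..L-1`, emits
#' the pair `sin(2^l * pi * c)`, `cos(2^l * pi * c)`; the 4L columns are
#' ordered x-bands then y-bands. Values are bounded in [-1, 1] and the map is
#' injective on any regular grid.
#'
#' @param coords N x 2 matrix of 0-based (x, y) grid positions.
#' @param grid integer (W, H) of the grid, for center-of-pixel normalization
#'   `(x + 0.5) / W`.
#' @param L band count, default 8.
#' @return N x 4L matrix.
#' @export
positional_encoding <- function(coords, grid, L = 8L) {
  stopifnot(L >= 1L)
  xn <- (coords[, 1] + 0.5) / grid[1]
  yn <- (coords[, 2] + 0.5) / grid[2]
  out <- matrix(0, nrow(coords), 4L * L)
  for (l in seq_len(L) - 1L) {
    f <- 2^l * pi
    out[, 2L * l + 1L] <- sin(f * xn)
    out[, 2L * l + 2L] <- cos(f * xn)
    out[, 2L * L + 2L * l + 1L] <- sin(f * yn)
    out[, 2L * L + 2L * l + 2L] <- cos(f * yn)
  }
  out
}

#' Initialize the per-stage query projections
#' @param params backbone parameters (for stage widths).
#' @param hidden shared query width h.
#' @param pe_bands positional-encoding band count L.
#' @return list with per-stage linear maps and a shared encoding projection.
#' @export
init_projection <- function(params, hidden, pe_bands = 8L) {
  list(
    stages = lapply(params$widths, function(cw) linear_init(cw, hidden)),
    pe = linear_init(4L * pe_bands, hidden),
    hidden = as.integer(hidden), pe_bands = as.integer(pe_bands)
  )
}

#' Flatten one pyramid stage into a positional-encoded query matrix
#'
#' Row-major flattening (x fastest), linear projection to the shared hidden
#' width and elementwise addition of the projected positional encoding.
#' Token coordinates (stage resolution, 0-based) are kept for spatial
#' attention and decoding.
#'
#' @param pyramid from [extract_pyramid()].
#' @param stage stage index 1..4.
#' @param proj from [init_projection()].
#' @return object of class `query_matrix`: list with `queries` (N x h),
#'   `coords` (N x 2), `H`, `W`, `modality`, `stage`.
#' @export
flatten_project <- function(pyramid, stage, proj) {
  stopifnot(stage %in% 1:4)
  st <- pyramid$stages[[stage]]
  coords <- cbind(x = rep(seq_len(st$W) - 1L, times = st$H),
                  y = rep(seq_len(st$H) - 1L, each = st$W))
  pe <- positional_encoding(coords, c(st$W, st$H), proj$pe_bands)
  q <- linear_fwd(st$feat, proj$stages[[stage]]) + linear_fwd(pe, proj$pe)
  structure(list(queries = q, coords = coords, H = st$H, W = st$W,
                 modality = pyramid$modality, stage = stage),
            class = "query_matrix")
}
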