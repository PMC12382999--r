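# Minimal neural-network primitives on base R arrays. Feature maps are
# arrays [H, W, C]; token matrices are N x h with tokens flattened row-major
# (x fastest). Forward functions optionally return caches used by the
# hand-derived backward passes in train.R.

#' im2col index table for a convolution
#'
#' Returns a (Hout*Wout) x (kh*kw) matrix of linear indices into the
#' zero-padded [Hp, Wp] plane (0 index = padding, handled by the caller
#' prepending a zero), plus output geometry.
#' @noRd
im2col_index <- function(h, w, kh, kw, stride = 1L, pad = (kh - 1L) %/% 2L) {
  hout <- (h + 2L * pad - kh) %/% stride + 1L
  wout <- (w + 2L * pad - kw) %/% stride + 1L
  hp <- h + 2L * pad; wp <- w + 2L * pad
  # row-major token order (x fastest): token t -> (y = t %/% wout, x = t %% wout)
  oy <- rep(seq_len(hout) - 1L, each = wout)
  ox <- rep(seq_len(wout) - 1L, times = hout)
  dy <- rep(seq_len(kh) - 1L, times = kw)
  dx <- rep(seq_len(kw) - 1L, each = kh)
  ry <- outer(oy * stride, dy, "+") + 1L             # rows in padded plane
  rx <- outer(ox * stride, dx, "+") + 1L
  idx <- (rx - 1L) * hp + ry                          # column-major linear index
  list(idx = idx, hout = hout, wout = wout, hp = hp, wp = wp, pad = pad,
       kh = kh, kw = kw, stride = stride, h = h, w = w)
}

pad_plane <- function(m, pad) {
  if (pad == 0L) return(m)
  out <- matrix(0, nrow(m) + 2L * pad, ncol(m) + 2L * pad)
  out[(pad + 1L):(pad + nrow(m)), (pad + 1L):(pad + ncol(m))] <- m
  out
}

#' 2-D convolution (cross-correlation) with zero padding
#'
#' @param x array [H, W, Cin]
#' @param w array [kh, kw, Cin, Cout]
#' @param b length-Cout bias
#' @param stride integer stride
#' @param cache return im2col intermediates for backprop
#' @return array [Hout, Wout, Cout] (with attribute "cache" if requested)
#' @noRd
conv2d <- function(x, w, b = NULL, stride = 1L, cache = FALSE) {
  dn <- dim(x); h <- dn[1]; wd <- dn[2]; cin <- dn[3]
  kh <- dim(w)[1]; kw <- dim(w)[2]; cout <- dim(w)[4]
  ii <- im2col_index(h, wd, kh, kw, stride)
  n <- nrow(ii$idx)
  cols <- matrix(0, n, ii$kh * ii$kw * cin)
  for (ci in seq_len(cin)) {
    p <- pad_plane(x[, , ci], ii$pad)
    cols[, ((ci - 1L) * kh * kw + 1L):(ci * kh * kw)] <- p[ii$idx]
  }
  wm <- matrix(aperm(w, c(1, 2, 3, 4)), kh * kw * cin, cout)
  out <- cols %*% wm
  if (!is.null(b)) out <- sweep(out, 2L, b, "+")
  res <- array(0, dim = c(ii$hout, ii$wout, cout))
  # tokens are row-major (x fastest): token t -> (y = t %/% wout, x = t %% wout)
  for (co in seq_len(cout)) {
    res[, , co] <- matrix(out[, co], ii$hout, ii$wout, byrow = TRUE)
  }
  if (cache) attr(res, "cache") <- list(cols = cols, ii = ii, cin = cin)
  res
}

#' Gradients of conv2d w.r.t. weights, bias and input
#'
#' `gout` is the upstream gradient [Hout, Wout, Cout]; `cc` the forward cache.
#' @noRd
conv2d_backward <- function(gout, w, cc, need_input_grad = TRUE) {
  kh <- dim(w)[1]; kw <- dim(w)[2]; cin <- dim(w)[3]; cout <- dim(w)[4]
  ii <- cc$ii
  gmat <- matrix(0, nrow(cc$cols), cout)
  for (co in seq_len(cout)) gmat[, co] <- as.vector(t(gout[, , co]))
  gw <- array(t(cc$cols) %*% gmat, dim = c(kh, kw, cin, cout))
  gb <- colSums(gmat)
  gx <- NULL
  if (need_input_grad) {
    wm <- matrix(w, kh * kw * cin, cout)
    gcols <- gmat %*% t(wm)                       # n x (kh*kw*cin)
    gx <- array(0, dim = c(ii$h, ii$w, cin))
    hp <- ii$hp
    for (ci in seq_len(cin)) {
      gp <- numeric(hp * ii$wp)
      block <- gcols[, ((ci - 1L) * kh * kw + 1L):(ci * kh * kw), drop = FALSE]
      for (jj in seq_len(ncol(ii$idx))) {
        tgt <- ii$idx[, jj]
        gp[tgt] <- gp[tgt] + block[, jj]
      }
      gpm <- matrix(gp, hp, ii$wp)
      gx[, , ci] <- gpm[(ii$pad + 1L):(ii$pad + ii$h),
                        (ii$pad + 1L):(ii$pad + ii$w)]
    }
  }
  list(gw = gw, gb = gb, gx = gx)
}

linear_init <- function(nin, nout, scale = NULL) {
  list(W = rand_mat(nin, nout, scale), b = numeric(nout))
}

linear_fwd <- function(x, p) sweep(x %*% p$W, 2L, p$b, "+")

conv_init <- function(kh, kw, cin, cout, scale = NULL) {
  if (is.null(scale)) scale <- 1 / sqrt(kh * kw * cin)
  list(W = array(stats::rnorm(kh * kw * cin * cout, sd = scale),
                 dim = c(kh, kw, cin, cout)),
       b = numeric(cout))
}

#' One AdamW update over a flat named list of parameter arrays
#'
#' `state` holds first/second moments and the step counter; pass the result's
#' `state` back in. Decoupled weight decay, bias-corrected moments.
#' @noRd
adamw_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0.0) {
  if (is.null(state$t)) {
    state <- list(t = 0L, m = lapply(params, function(p) p * 0),
                  v = lapply(params, function(p) p * 0))
  }
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    if (is.null(g)) next
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    mhat <- state$m[[k]] / bc1
    vhat <- state$v[[k]] / bc2
    params[[k]] <- params[[k]] - lr * (mhat / (sqrt(vhat) + eps) +
                                       weight_decay * params[[k]])
  }
  list(params = params, state = state)
}

#' Cosine learning-rate schedule with linear warmup
#'
#' Returns the learning rate at 0-based `step`: linear ramp to `peak` over
#' `warmup` steps, then cosine annealing to 0 at `total` steps.
#' @param step 0-based optimizer step (after warmup, step 0 of the cosine
#'   phase returns exactly `peak`).
#' @param peak peak learning rate.
#' @param warmup warmup step count.
#' @param total total cosine steps after warmup.
#' @export
lr_schedule <- function(step, peak, warmup = 1000L, total = 10000L) {
  if (warmup > 0L && step < warmup) return(peak * (step + 1) / warmup)
  s <- step - warmup
  peak * 0.5 * (1 + cos(pi * min(s / max(total, 1L), 1)))
}
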