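# Unified detection-tracking head: center heatmap / box / refinement-offset
# branches on the fused query grid, displacement prediction for track
# queries, learned pairwise affinity with Hungarian matching, cross-modal
# confidence fusion, and the five-term multi-task loss.

#' Initialize detection-head parameters
#'
#' One parameter set, applied to each modality's fused grid.
#' @param hidden fused query width h (input channels of the head).
#' @return parameter list for the three convolutional branches, the
#'   displacement MLP and the affinity network.
#' @export
init_head <- function(hidden) {
  h <- as.integer(hidden)
  structure(list(
    heat1 = conv_init(1L, 1L, h, h), heat2 = conv_init(3L, 3L, h, 1L),
    box1 = conv_init(3L, 3L, h, h),  box2 = conv_init(1L, 1L, h, 4L),
    off1 = conv_init(3L, 3L, h, h),  off2 = conv_init(1L, 1L, h, 2L),
    disp1 = linear_init(h, 2L * h), disp2 = linear_init(2L * h, 2L),
    affinity = affinity_identity_params(h, noise = 0.02),
    hidden = h
  ), class = "head_params")
}

queries_to_grid <- function(fused_block, H, W) {
  h <- ncol(fused_block)
  g <- array(0, dim = c(H, W, h))
  for (ci in seq_len(h)) g[, , ci] <- matrix(fused_block[, ci], H, W, byrow = TRUE)
  g
}

#' Detection head forward pass
#'
#' Three convolutional branches on a fused feature grid:
#' heatmap `H = sigmoid(conv3x3(relu(conv1x1(x))))`, boxes
#' `B = conv1x1(relu(conv3x3(x)))` (4 channels: center refinements and
#' width/height in pixels), offsets `O = tanh(conv1x1(relu(conv3x3(x))))`.
#'
#' @param grid array [H, W, h] of fused queries (see `queries_to_grid`
#'   internally, or pass `fused$D_a` reshaped).
#' @param p head parameters.
#' @return list with `heatmap` (H x W in (0,1)), `boxes` [H, W, 4],
#'   `offsets` [H, W, 2] in (-1,1).
#' @export
detection_head <- function(grid, p) {
  hm <- conv2d(relu(conv2d(grid, p$heat1$W, p$heat1$b)), p$heat2$W, p$heat2$b)
  bx <- conv2d(relu(conv2d(grid, p$box1$W, p$box1$b)), p$box2$W, p$box2$b)
  of <- conv2d(relu(conv2d(grid, p$off1$W, p$off1$b)), p$off2$W, p$off2$b)
  list(heatmap = sigmoid(hm[, , 1]), boxes = bx, offsets = tanh(of))
}

#' Decode peak detections from head outputs
#'
#' Local maxima of the (combined) heatmap over 3x3 neighborhoods, thresholded
#' and truncated to the `max_det` strongest; ties break by (score descending,
#' y ascending, x ascending). Centers are refined by the offset branch and
#' mapped to pixels through the stage stride; box width/height are read from
#' the box branch at the peak and clamped nonnegative.
#'
#' @param heatmap combined score map (H x W).
#' @param boxes,offsets branch outputs as from [detection_head()].
#' @param stride stage downsampling ratio (pixels per grid cell).
#' @param score_thresh minimum peak score in (0,1).
#' @param max_det maximum detections returned.
#' @param c_a,c_m optional per-modality heatmaps for modality confidences.
#' @return data.frame with columns `gx`, `gy` (grid cell), `cx`, `cy`
#'   (pixel center), `w`, `h` (pixels), `score`, `c_a`, `c_m`, `token`
#'   (row-major token index of the peak).
#' @export
decode_detections <- function(heatmap, boxes, offsets, stride = 4L,
                              score_thresh = 0.3, max_det = 100L,
                              c_a = NULL, c_m = NULL) {
  stopifnot(score_thresh > 0, score_thresh < 1)
  H <- nrow(heatmap); W <- ncol(heatmap)
  pad <- matrix(-Inf, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- heatmap
  ismax <- matrix(TRUE, H, W)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- pad[(2:(H + 1L)) + dy, (2:(W + 1L)) + dx]
    # strict on earlier-scanning neighbors so a flat plateau yields one peak
    if (dy < 0 || (dy == 0 && dx < 0)) ismax <- ismax & (heatmap > nb)
    else ismax <- ismax & (heatmap >= nb)
  }
  idx <- which(ismax & heatmap >= score_thresh)
  if (!length(idx)) {
    return(data.frame(gx = integer(), gy = integer(), cx = numeric(),
                      cy = numeric(), w = numeric(), h = numeric(),
                      score = numeric(), c_a = numeric(), c_m = numeric(),
                      token = integer()))
  }
  gy <- (idx - 1L) %% H
  gx <- (idx - 1L) %/% H
  sc <- heatmap[idx]
  ord <- order(-sc, gy, gx)
  keep <- ord[seq_len(min(length(ord), max_det))]
  gy <- gy[keep]; gx <- gx[keep]; sc <- sc[keep]
  li <- cbind(gy + 1L, gx + 1L)
  ox <- offsets[cbind(li, 1L)]; oy <- offsets[cbind(li, 2L)]
  bw <- pmax(boxes[cbind(li, 3L)], 0); bh <- pmax(boxes[cbind(li, 4L)], 0)
  data.frame(
    gx = gx, gy = gy,
    cx = (gx + ox) * stride + (stride - 1) / 2,
    cy = (gy + oy) * stride + (stride - 1) / 2,
    w = bw, h = bh, score = sc,
    c_a = if (is.null(c_a)) sc else c_a[li],
    c_m = if (is.null(c_m)) sc else c_m[li],
    token = gy * W + gx + 1L
  )
}

#' Predict per-track displacement from trajectory memory
#'
#' Two-layer perceptron `h -> 2h -> 2`; the predicted position update is
#' `p_k = p_{k-1} + delta`. Motion uncertainty is a training-time noise
#' model only: inference uses the mean.
#' @param memory N_t x h track memory matrix.
#' @param p head parameters.
#' @return N_t x 2 matrix of (dx, dy) in pixels.
#' @export
predict_displacement <- function(memory, p) {
  if (ncol(memory) != nrow(p$disp1$W)) {
    stop("memory width ", ncol(memory), " != head hidden ", nrow(p$disp1$W),
         call. = FALSE)
  }
  linear_fwd(relu(linear_fwd(memory, p$disp1)), p$disp2)
}

#' Structured initialization of the affinity network
#'
#' Builds two-layer weights implementing (up to small noise) the score
#' `s = 2 - (4 / h) * sum(|U - V|)`: high for similar embeddings, decreasing
#' in their L1 distance. Gives an untrained tracker a usable similarity prior;
#' training updates these weights like any others.
#' @param h embedding width.
#' @param noise sd of Gaussian perturbation added to all weights.
#' @export
affinity_identity_params <- function(h, noise = 0) {
  W1 <- matrix(0, 4L * h, h)
  W1[(3L * h + 1L):(4L * h), ] <- diag(h)
  b1 <- numeric(h)
  W2 <- matrix(-4 / h, h, 1L)
  b2 <- 2
  if (noise > 0) {
    W1 <- W1 + matrix(stats::rnorm(length(W1), sd = noise), nrow(W1))
    W2 <- W2 + matrix(stats::rnorm(length(W2), sd = noise), nrow(W2))
    b1 <- b1 + stats::rnorm(h, sd = noise)
  }
  list(l1 = list(W = W1, b = b1), l2 = list(W = W2, b = b2))
}

#' Pairwise detection-track affinity
#'
#' For every detection embedding `U_i` and track embedding `V_j`, scores the
#' pair through a two-layer network on the interaction feature
#' `[U; V; U*V; |U - V|]` and squashes with a sigmoid.
#' @param U N_d x h detection embeddings.
#' @param V N_t x h track embeddings.
#' @param p affinity parameters (`l1`, `l2`).
#' @return object of class `affinity_matrix`: list with `A` (sigmoid scores
#'   in (0,1)) and raw scores `s`, both N_d x N_t.
#' @export
affinity <- function(U, V, p) {
  if (ncol(U) != ncol(V)) stop("embedding widths differ", call. = FALSE)
  nd <- nrow(U); nt <- nrow(V)
  if (nd == 0L || nt == 0L) {
    s <- matrix(numeric(), nd, nt)
    return(structure(list(A = s, s = s), class = "affinity_matrix"))
  }
  iu <- rep(seq_len(nd), times = nt)
  iv <- rep(seq_len(nt), each = nd)
  Ub <- U[iu, , drop = FALSE]; Vb <- V[iv, , drop = FALSE]
  feat <- cbind(Ub, Vb, Ub * Vb, abs(Ub - Vb))
  s <- matrix(linear_fwd(relu(linear_fwd(feat, p$l1)), p$l2), nd, nt)
  structure(list(A = sigmoid(s), s = s), class = "affinity_matrix")
}

#' Hungarian matching of detections to tracks
#'
#' Maximum-total-affinity one-to-one assignment; pairs whose affinity falls
#' below `accept_thresh` (or that were gated out, entries of `-Inf`) are
#' moved to the unmatched lists after assignment.
#' @param A affinity matrix (an `affinity_matrix` object or plain matrix,
#'   optionally containing `-Inf` for forbidden pairs).
#' @param accept_thresh minimum accepted affinity.
#' @return object of class `match_set`: list with `pairs` (2-column matrix of
#'   detection/track indices), `unmatched_det`, `unmatched_track`.
#' @export
match_detections <- function(A, accept_thresh = 0.3) {
  if (inherits(A, "affinity_matrix")) A <- A$A
  nd <- nrow(A); nt <- ncol(A)
  assign <- if (nd && nt) solve_assignment_max(A) else rep(NA_integer_, nd)
  pairs <- NULL
  for (i in seq_len(nd)) {
    j <- assign[i]
    if (!is.na(j) && is.finite(A[i, j]) && A[i, j] >= accept_thresh) {
      pairs <- rbind(pairs, c(i, j))
    }
  }
  if (is.null(pairs)) pairs <- matrix(integer(), 0L, 2L)
  colnames(pairs) <- c("det", "track")
  structure(list(
    pairs = pairs,
    unmatched_det = setdiff(seq_len(nd), pairs[, 1]),
    unmatched_track = setdiff(seq_len(nt), pairs[, 2])
  ), class = "match_set")
}

#' Cross-modal confidence fusion
#'
#' Harmonic mean of the modality confidences,
#' `c_h = 2 c_a c_m / (c_a + c_m + eps)`, then
#' `fused = det_score * sigmoid(gamma * c_h)`. The harmonic mean punishes
#' disagreement: one vanishing modality drags the factor to 1/2.
#' All arguments vectorize.
#' @param det_score detection score(s) in (0,1].
#' @param c_a,c_m modality confidences in [0,1].
#' @param gamma sharpening factor, default 2.
#' @param eps stabilizer, default 1e-6.
#' @export
fuse_confidence <- function(det_score, c_a, c_m, gamma = 2.0, eps = 1e-6) {
  ch <- 2 * c_a * c_m / (c_a + c_m + eps)
  det_score / (1 + exp(-gamma * ch))
}

#' Intersection-over-union of axis-aligned boxes
#'
#' Boxes are (left, top, width, height); both arguments vectorize row-wise.
#' @param a,b 4-column matrices (or length-4 vectors).
#' @return numeric vector of IoU values in [0, 1].
#' @export
box_iou <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, 1L)
  if (is.null(dim(b))) b <- matrix(b, 1L)
  ix <- pmax(0, pmin(a[, 1] + a[, 3], b[, 1] + b[, 3]) - pmax(a[, 1], b[, 1]))
  iy <- pmax(0, pmin(a[, 2] + a[, 4], b[, 2] + b[, 4]) - pmax(a[, 2], b[, 2]))
  inter <- ix * iy
  un <- a[, 3] * a[, 4] + b[, 3] * b[, 4] - inter
  ifelse(un > 0, inter / un, 0)
}

smooth_l1 <- function(x) ifelse(abs(x) < 1, 0.5 * x^2, abs(x) - 0.5)

#' Multi-task loss bundle
#'
#' Five unweighted terms: `L_cf` penalty-reduced focal loss on the center
#' heatmap (shape parameters `focal_alpha`, `focal_beta`), `L_bs` SmoothL1 on
#' box regressions at object centers, `L_r` L1 on refinement offsets at
#' centers, `L_td` mean `1 - IoU` between displaced and true track boxes, and
#' `L_match` binary cross-entropy on the (pre-threshold) affinity matrix
#' against ground-truth assignment labels.
#'
#' @param pred list: `heatmap` (H x W), `boxes` [H,W,4], `offsets` [H,W,2],
#'   `disp_boxes` / `true_boxes` (N x 4 ltwh matrices, may have 0 rows),
#'   `affinity` (N_d x N_t probabilities, may be 0 x 0).
#' @param target list: `heatmap` (Gaussian-splatted in [0,1]), `boxes`
#'   [H,W,4], `offsets` [H,W,2], `center_mask` (H x W logical),
#'   `match` (0/1 matrix shaped like `pred$affinity`).
#' @param focal_alpha,focal_beta focal shape parameters (defaults 2, 4).
#' @return object of class `loss_bundle`: list with `L_cf`, `L_bs`, `L_r`,
#'   `L_td`, `L_match`, `total`.
#' @export
compute_losses <- function(pred, target, focal_alpha = 2, focal_beta = 4) {
  if (!identical(dim(pred$heatmap), dim(target$heatmap))) {
    stop("heatmap shapes differ", call. = FALSE)
  }
  eps <- 1e-9
  H <- pmin(pmax(pred$heatmap, eps), 1 - eps)
  Tm <- target$heatmap
  pos <- Tm >= 1 - 1e-12
  npos <- max(sum(pos), 1)
  l_pos <- -sum(((1 - H)^focal_alpha * log(H))[pos])
  l_neg <- -sum(((1 - Tm)^focal_beta * H^focal_alpha * log(1 - H))[!pos])
  L_cf <- (l_pos + l_neg) / npos

  cm <- which(target$center_mask)
  if (length(cm)) {
    db <- vapply(1:4, function(c3) {
      p <- pred$boxes[, , c3][cm] - target$boxes[, , c3][cm]
      sum(smooth_l1(p))
    }, numeric(1))
    L_bs <- sum(db) / (4 * length(cm))
    do <- vapply(1:2, function(c3) {
      sum(abs(pred$offsets[, , c3][cm] - target$offsets[, , c3][cm]))
    }, numeric(1))
    L_r <- sum(do) / (2 * length(cm))
  } else {
    L_bs <- 0; L_r <- 0
  }

  if (!is.null(pred$disp_boxes) && nrow(pred$disp_boxes)) {
    L_td <- mean(1 - box_iou(pred$disp_boxes, pred$true_boxes))
  } else L_td <- 0

  if (!is.null(pred$affinity) && length(pred$affinity)) {
    A <- pmin(pmax(pred$affinity, eps), 1 - eps)
    Y <- target$match
    if (!identical(dim(A), dim(Y))) stop("affinity shapes differ", call. = FALSE)
    L_match <- -mean(Y * log(A) + (1 - Y) * log(1 - A))
  } else L_match <- 0

  out <- list(L_cf = L_cf, L_bs = L_bs, L_r = L_r, L_td = L_td,
              L_match = L_match)
  out$total <- L_cf + L_bs + L_r + L_td + L_match
  class(out) <- "loss_bundle"
  out
}

#' Render dense training targets from ground-truth boxes
#'
#' Splats a Gaussian peak per object on the stage grid (CenterNet-style
#' radius from the box size), writes box and offset regression targets at the
#' center cell, and marks center cells.
#' @param boxes N x 4 ltwh pixel boxes.
#' @param H,W stage grid size.
#' @param stride stage downsampling ratio.
#' @return target list as consumed by [compute_losses()].
#' @export
render_targets <- function(boxes, H, W, stride = 4L) {
  hm <- matrix(0, H, W)
  bt <- array(0, dim = c(H, W, 4))
  ot <- array(0, dim = c(H, W, 2))
  mask <- matrix(FALSE, H, W)
  if (is.null(dim(boxes))) boxes <- matrix(boxes, ncol = 4L)
  n <- nrow(boxes)
  for (i in seq_len(n)) {
    cx <- (boxes[i, 1] + boxes[i, 3] / 2 - (stride - 1) / 2) / stride
    cy <- (boxes[i, 2] + boxes[i, 4] / 2 - (stride - 1) / 2) / stride
    gx <- min(max(round(cx), 0), W - 1L)
    gy <- min(max(round(cy), 0), H - 1L)
    r <- max(1, floor(min(boxes[i, 3], boxes[i, 4]) / (2 * stride)))
    sg <- max(r / 3, 0.6)
    ys <- max(0, gy - 3 * r):min(H - 1L, gy + 3 * r)
    xs <- max(0, gx - 3 * r):min(W - 1L, gx + 3 * r)
    g <- exp(-(outer((ys - cy)^2, (xs - cx)^2, "+")) / (2 * sg^2))
    hm[ys + 1L, xs + 1L] <- pmax(hm[ys + 1L, xs + 1L], g)
    hm[gy + 1L, gx + 1L] <- 1
    mask[gy + 1L, gx + 1L] <- TRUE
    bt[gy + 1L, gx + 1L, ] <- c(0, 0, boxes[i, 3], boxes[i, 4])
    ot[gy + 1L, gx + 1L, ] <- pmin(pmax(c(cx - gx, cy - gy), -0.999), 0.999)
  }
  list(heatmap = hm, boxes = bt, offsets = ot, center_mask = mask)
}
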