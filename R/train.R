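# Desk-scale training of the detection-tracking head on simulated sequences.
# The backbone + graph-fusion trunk is frozen (random features are already
# discriminative at this scale); the convolutional branches, displacement
# MLP and affinity network are optimized with hand-derived analytic
# gradients under AdamW with decoupled weight decay and a warmup + cosine
# schedule. The full-scale recipe's optimizer family, weight decay and
# augmentation are kept; the learning rate and step count are rescaled for a
# 200-step CPU run.

#' Frozen-trunk features for one frame pair
#'
#' Runs motion decoupling, both backbones and the graph encoder (zero
#' trajectory memory) and returns the fused per-modality grids.
#' @param frame_prev,frame_cur frames.
#' @param model a `mot_model`.
#' @param config full config.
#' @return list with `grid_a`, `grid_m` ([H,W,h]), `mix` token matrix,
#'   `H`, `W`, `stride`.
#' @export
extract_pair_features <- function(frame_prev, frame_cur, model,
                                  config = model$config) {
  if (isTRUE(config$tracker$use_motion) && !identical(frame_prev, frame_cur)) {
    raster <- motion_features(frame_prev, frame_cur, config$motion)$raster
  } else {
    raster <- array(0, dim = c(dim(frame_cur), 2L))
  }
  stage <- min(config$model$stages_used)
  D_a <- flatten_project(extract_pyramid(frame_cur, model$backbone_a, "appearance"),
                         stage, model$proj_a)
  D_m <- flatten_project(extract_pyramid(raster, model$backbone_m, "motion"),
                         stage, model$proj_m)
  if (isTRUE(config$tracker$use_mhgn)) {
    fused <- mhgn_encode(build_graph(D_a, D_m, NULL, NULL,
                                     config$mhgn$k_spatial), model$mhgn)
  } else {
    fused <- list(D_a = D_a$queries, D_m = D_m$queries)
  }
  list(grid_a = queries_to_grid(fused$D_a, D_a$H, D_a$W),
       grid_m = queries_to_grid(fused$D_m, D_m$H, D_m$W),
       mix = (fused$D_a + fused$D_m) / 2,
       H = D_a$H, W = D_a$W, stride = STAGE_RATIOS[stage])
}

#' Rotate an image about its center (bilinear, reflection fill)
#' @noRd
rotate_image <- function(m, deg) {
  th <- deg * pi / 180
  h <- nrow(m); w <- ncol(m)
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  xg <- matrix(0:(w - 1), h, w, byrow = TRUE) - cx
  yg <- matrix(0:(h - 1), h, w) - cy
  xs <- cos(th) * xg + sin(th) * yg + cx
  ys <- -sin(th) * xg + cos(th) * yg + cy
  matrix(bilinear_sample(m, as.vector(xs), as.vector(ys)), h, w)
}

rotate_boxes <- function(boxes, deg, w, h) {
  th <- deg * pi / 180
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  bx <- boxes[, 1] + boxes[, 3] / 2 - cx
  by <- boxes[, 2] + boxes[, 4] / 2 - cy
  nx <- cos(th) * bx - sin(th) * by + cx
  ny <- sin(th) * bx + cos(th) * by + cy
  cbind(nx - boxes[, 3] / 2, ny - boxes[, 4] / 2, boxes[, 3], boxes[, 4])
}

build_training_pairs <- function(sim, model, config, augment = TRUE) {
  n <- length(sim$frames)
  gt <- sim$gt
  W <- sim$config$width; H <- sim$config$height
  pairs <- list()
  for (k in 2:n) {
    g_cur <- gt[gt$frame == k - 1L & gt$visible, , drop = FALSE]
    g_prev <- gt[gt$frame == k - 2L & gt$visible, , drop = FALSE]
    variants <- list(list(fp = sim$frames[[k - 1L]], fc = sim$frames[[k]],
                          cur = g_cur, prev = g_prev))
    if (augment) {
      flip <- isTRUE(config$train$aug_flip) && stats::runif(1) < 0.5
      deg <- if (config$train$aug_rot_deg > 0)
        stats::runif(1, -config$train$aug_rot_deg, config$train$aug_rot_deg) else 0
      fp <- sim$frames[[k - 1L]]; fc <- sim$frames[[k]]
      tc <- g_cur; tp <- g_prev
      if (flip) {
        fp <- fp[, ncol(fp):1]; fc <- fc[, ncol(fc):1]
        tc$x <- W - tc$x - tc$w; tp$x <- W - tp$x - tp$w
      }
      if (abs(deg) > 1e-9) {
        fp <- rotate_image(fp, deg); fc <- rotate_image(fc, deg)
        bc <- rotate_boxes(as.matrix(tc[, c("x", "y", "w", "h")]), deg, W, H)
        tc[, c("x", "y", "w", "h")] <- bc
        if (nrow(tp)) {
          bp <- rotate_boxes(as.matrix(tp[, c("x", "y", "w", "h")]), deg, W, H)
          tp[, c("x", "y", "w", "h")] <- bp
        }
      }
      variants <- c(variants, list(list(fp = fp, fc = fc, cur = tc, prev = tp)))
    }
    for (v in variants) {
      fe <- extract_pair_features(v$fp, v$fc, model, config)
      tg <- render_targets(as.matrix(v$cur[, c("x", "y", "w", "h")]),
                           fe$H, fe$W, fe$stride)
      common <- intersect(v$cur$id, v$prev$id)
      tok_of <- function(bx, by, bw, bh) {
        gx <- pmin(pmax(round((bx + bw / 2 - (fe$stride - 1) / 2) / fe$stride), 0), fe$W - 1)
        gy <- pmin(pmax(round((by + bh / 2 - (fe$stride - 1) / 2) / fe$stride), 0), fe$H - 1)
        gy * fe$W + gx + 1L
      }
      cc <- v$cur[match(common, v$cur$id), , drop = FALSE]
      pc <- v$prev[match(common, v$prev$id), , drop = FALSE]
      U <- fe$mix[tok_of(cc$x, cc$y, cc$w, cc$h), , drop = FALSE]
      Vp <- fe$mix[tok_of(pc$x, pc$y, pc$w, pc$h), , drop = FALSE]
      pairs[[length(pairs) + 1L]] <- list(
        grid_a = fe$grid_a, grid_m = fe$grid_m, target = tg,
        U = U, V = Vp,
        match_lab = diag(nrow = length(common)),
        prev_boxes = as.matrix(pc[, c("x", "y", "w", "h")]),
        cur_boxes = as.matrix(cc[, c("x", "y", "w", "h")]))
    }
  }
  pairs
}

focal_grad <- function(p, Tm, a, b, npos) {
  pos <- Tm >= 1 - 1e-12
  eps <- 1e-9
  p <- pmin(pmax(p, eps), 1 - eps)
  g <- matrix(0, nrow(p), ncol(p))
  gp <- a * (1 - p)^(a - 1) * log(p) - (1 - p)^a / p
  gn <- -(1 - Tm)^b * (a * p^(a - 1) * log(1 - p) - p^a / (1 - p))
  g[pos] <- gp[pos]
  g[!pos] <- gn[!pos]
  g * p * (1 - p) / npos       # chain through the sigmoid, focal normalization
}

# forward + analytic backward of the three conv branches on one grid.
# Returns loss terms and gradients keyed like `params`.
head_branch_grads <- function(grid, params, target, cfg_head,
                              box_branches = TRUE) {
  g <- list()
  y1 <- conv2d(grid, params$heat1$W, params$heat1$b, cache = TRUE)
  a1 <- relu(y1)
  y2 <- conv2d(a1, params$heat2$W, params$heat2$b, cache = TRUE)
  p <- sigmoid(y2[, , 1])
  npos <- max(sum(target$heatmap >= 1 - 1e-12), 1)
  eps <- 1e-9
  pc <- pmin(pmax(p, eps), 1 - eps)
  pos <- target$heatmap >= 1 - 1e-12
  L_cf <- (-sum(((1 - pc)^cfg_head$focal_alpha * log(pc))[pos]) -
           sum(((1 - target$heatmap)^cfg_head$focal_beta * pc^cfg_head$focal_alpha *
                log(1 - pc))[!pos])) / npos
  gy2 <- array(focal_grad(p, target$heatmap, cfg_head$focal_alpha,
                          cfg_head$focal_beta, npos), dim = dim(y2))
  bk2 <- conv2d_backward(gy2, params$heat2$W, attr(y2, "cache"))
  ga1 <- bk2$gx * (y1 > 0)
  bk1 <- conv2d_backward(ga1, params$heat1$W, attr(y1, "cache"),
                         need_input_grad = FALSE)
  g$heat1.W <- bk1$gw; g$heat1.b <- bk1$gb
  g$heat2.W <- bk2$gw; g$heat2.b <- bk2$gb

  L_bs <- 0; L_r <- 0
  if (box_branches) {
    cm <- which(target$center_mask)
    ncm <- max(length(cm), 1)
    # box branch
    y1b <- conv2d(grid, params$box1$W, params$box1$b, cache = TRUE)
    a1b <- relu(y1b)
    y2b <- conv2d(a1b, params$box2$W, params$box2$b, cache = TRUE)
    gy2b <- array(0, dim = dim(y2b))
    for (c3 in 1:4) {
      diff <- y2b[, , c3][cm] - target$boxes[, , c3][cm]
      L_bs <- L_bs + sum(smooth_l1(diff))
      gch <- matrix(0, dim(y2b)[1], dim(y2b)[2])
      gch[cm] <- pmin(pmax(diff, -1), 1) / (4 * ncm)
      gy2b[, , c3] <- gch
    }
    L_bs <- L_bs / (4 * ncm)
    bk2b <- conv2d_backward(gy2b, params$box2$W, attr(y2b, "cache"))
    ga1b <- bk2b$gx * (y1b > 0)
    bk1b <- conv2d_backward(ga1b, params$box1$W, attr(y1b, "cache"),
                            need_input_grad = FALSE)
    g$box1.W <- bk1b$gw; g$box1.b <- bk1b$gb
    g$box2.W <- bk2b$gw; g$box2.b <- bk2b$gb
    # offset branch
    y1o <- conv2d(grid, params$off1$W, params$off1$b, cache = TRUE)
    a1o <- relu(y1o)
    y2o <- conv2d(a1o, params$off2$W, params$off2$b, cache = TRUE)
    O <- tanh(y2o)
    gy2o <- array(0, dim = dim(y2o))
    for (c3 in 1:2) {
      diff <- O[, , c3][cm] - target$offsets[, , c3][cm]
      L_r <- L_r + sum(abs(diff))
      gch <- matrix(0, dim(y2o)[1], dim(y2o)[2])
      gch[cm] <- sign(diff) * (1 - O[, , c3][cm]^2) / (2 * ncm)
      gy2o[, , c3] <- gch
    }
    L_r <- L_r / (2 * ncm)
    bk2o <- conv2d_backward(gy2o, params$off2$W, attr(y2o, "cache"))
    ga1o <- bk2o$gx * (y1o > 0)
    bk1o <- conv2d_backward(ga1o, params$off1$W, attr(y1o, "cache"),
                            need_input_grad = FALSE)
    g$off1.W <- bk1o$gw; g$off1.b <- bk1o$gb
    g$off2.W <- bk2o$gw; g$off2.b <- bk2o$gb
  }
  list(L_cf = L_cf, L_bs = L_bs, L_r = L_r, grads = g)
}

disp_affinity_grads <- function(pair, params) {
  g <- list(); L_td <- 0; L_match <- 0
  n <- nrow(pair$V)
  if (n) {
    z1 <- sweep(pair$V %*% params$disp1$W, 2, params$disp1$b, "+")
    a1 <- relu(z1)
    d <- sweep(a1 %*% params$disp2$W, 2, params$disp2$b, "+")
    disp_box <- pair$prev_boxes
    disp_box[, 1] <- disp_box[, 1] + d[, 1]
    disp_box[, 2] <- disp_box[, 2] + d[, 2]
    ious <- box_iou(disp_box, pair$cur_boxes)
    L_td <- mean(1 - ious)
    # dIoU/d(dx,dy): central differences (IoU is piecewise bilinear)
    gd <- matrix(0, n, 2)
    hstep <- 1e-4
    for (c2 in 1:2) {
      bp <- disp_box; bp[, c2] <- bp[, c2] + hstep
      bm <- disp_box; bm[, c2] <- bm[, c2] - hstep
      gd[, c2] <- -(box_iou(bp, pair$cur_boxes) -
                    box_iou(bm, pair$cur_boxes)) / (2 * hstep) / n
    }
    g$disp2.W <- t(a1) %*% gd
    g$disp2.b <- colSums(gd)
    ga1 <- (gd %*% t(params$disp2$W)) * (z1 > 0)
    g$disp1.W <- t(pair$V) %*% ga1
    g$disp1.b <- colSums(ga1)

    nd <- nrow(pair$U); nt <- n
    iu <- rep(seq_len(nd), times = nt); iv <- rep(seq_len(nt), each = nd)
    Ub <- pair$U[iu, , drop = FALSE]; Vb <- pair$V[iv, , drop = FALSE]
    feat <- cbind(Ub, Vb, Ub * Vb, abs(Ub - Vb))
    z1a <- sweep(feat %*% params$affinity$l1$W, 2, params$affinity$l1$b, "+")
    a1a <- relu(z1a)
    s <- sweep(a1a %*% params$affinity$l2$W, 2, params$affinity$l2$b, "+")
    A <- sigmoid(s)
    Y <- as.vector(pair$match_lab)
    eps <- 1e-9
    Ac <- pmin(pmax(A, eps), 1 - eps)
    L_match <- -mean(Y * log(Ac) + (1 - Y) * log(1 - Ac))
    ds <- matrix((A - Y) / length(A), ncol = 1)
    g$affinity.l2.W <- t(a1a) %*% ds
    g$affinity.l2.b <- sum(ds)
    ga1a <- (ds %*% t(params$affinity$l2$W)) * (z1a > 0)
    g$affinity.l1.W <- t(feat) %*% ga1a
    g$affinity.l1.b <- colSums(ga1a)
  }
  list(L_td = L_td, L_match = L_match, grads = g)
}

head_flat_params <- function(p) {
  list(heat1.W = p$heat1$W, heat1.b = p$heat1$b,
       heat2.W = p$heat2$W, heat2.b = p$heat2$b,
       box1.W = p$box1$W, box1.b = p$box1$b,
       box2.W = p$box2$W, box2.b = p$box2$b,
       off1.W = p$off1$W, off1.b = p$off1$b,
       off2.W = p$off2$W, off2.b = p$off2$b,
       disp1.W = p$disp1$W, disp1.b = p$disp1$b,
       disp2.W = p$disp2$W, disp2.b = p$disp2$b,
       affinity.l1.W = p$affinity$l1$W, affinity.l1.b = p$affinity$l1$b,
       affinity.l2.W = p$affinity$l2$W, affinity.l2.b = p$affinity$l2$b)
}

head_unflat_params <- function(p, flat) {
  p$heat1$W <- flat$heat1.W; p$heat1$b <- flat$heat1.b
  p$heat2$W <- flat$heat2.W; p$heat2$b <- flat$heat2.b
  p$box1$W <- flat$box1.W; p$box1$b <- flat$box1.b
  p$box2$W <- flat$box2.W; p$box2$b <- flat$box2.b
  p$off1$W <- flat$off1.W; p$off1$b <- flat$off1.b
  p$off2$W <- flat$off2.W; p$off2$b <- flat$off2.b
  p$disp1$W <- flat$disp1.W; p$disp1$b <- flat$disp1.b
  p$disp2$W <- flat$disp2.W; p$disp2$b <- flat$disp2.b
  p$affinity$l1$W <- flat$affinity.l1.W; p$affinity$l1$b <- flat$affinity.l1.b
  p$affinity$l2$W <- flat$affinity.l2.W; p$affinity$l2$b <- flat$affinity.l2.b
  p
}

# full-batch loss and gradients of the head on a list of training pairs
head_loss_grads <- function(pairs, params, cfg_head, with_grads = TRUE) {
  tot <- list(L_cf = 0, L_bs = 0, L_r = 0, L_td = 0, L_match = 0)
  acc <- NULL
  addg <- function(acc, g, scale) {
    if (is.null(acc)) acc <- lapply(g, function(x) x * scale)
    else for (k in names(g)) acc[[k]] <- (acc[[k]] %||% 0) + g[[k]] * scale
    acc
  }
  np <- length(pairs)
  for (pr in pairs) {
    ba <- head_branch_grads(pr$grid_a, params, pr$target, cfg_head, TRUE)
    bm <- head_branch_grads(pr$grid_m, params, pr$target, cfg_head, FALSE)
    da <- disp_affinity_grads(pr, params)
    tot$L_cf <- tot$L_cf + (ba$L_cf + bm$L_cf) / 2 / np
    tot$L_bs <- tot$L_bs + ba$L_bs / np
    tot$L_r <- tot$L_r + ba$L_r / np
    tot$L_td <- tot$L_td + da$L_td / np
    tot$L_match <- tot$L_match + da$L_match / np
    if (with_grads) {
      acc <- addg(acc, ba$grads, 1 / np)
      # heatmap grads of the motion stream share the heat weights
      hm <- bm$grads[c("heat1.W", "heat1.b", "heat2.W", "heat2.b")]
      acc <- addg(acc, hm, 1 / np)
      # both modality heat losses are halved
      for (k in c("heat1.W", "heat1.b", "heat2.W", "heat2.b")) {
        acc[[k]] <- acc[[k]] / 2
      }
      acc <- addg(acc, da$grads, 1 / np)
    }
  }
  tot$total <- tot$L_cf + tot$L_bs + tot$L_r + tot$L_td + tot$L_match
  list(loss = tot, grads = acc)
}

#' Tiny CPU training of the detection-tracking head
#'
#' Freezes the feature trunk, precomputes fused grids for every consecutive
#' frame pair of a simulated sequence (plus one flip/rotation-augmented
#' variant per pair), and optimizes the five-term multi-task loss over the
#' head parameters with AdamW (decoupled weight decay from the config) and a
#' warmup + cosine schedule. The last 20% of pairs are held out; their loss
#' is reported at initialization and after training.
#'
#' @param sim a `sim_sequence`.
#' @param config full config.
#' @param steps optimizer steps (default `config$train$steps`).
#' @param lr peak learning rate. The full-scale recipe's 2e-4 belongs to a
#'   ~50k-step GPU schedule; the desk default 0.02 scales it to a 200-step
#'   run and is fixed, not tuned.
#' @param augment add augmented variants (flip / rotation from config).
#' @return list with `model` (weights updated), `loss_history`,
#'   `loss_init`, `loss_final`, `holdout_init`, `holdout_final`.
#' @export
train_tiny <- function(sim, config = default_config(), steps = config$train$steps,
                       lr = 0.02, augment = TRUE) {
  if (!length(sim$frames)) stop("empty dataset", call. = FALSE)
  model <- init_model(config)
  with_seed(config$seed + 1L, {
    pairs <- build_training_pairs(sim, model, config, augment)
    nho <- max(1L, floor(0.2 * length(pairs)))
    ho <- pairs[(length(pairs) - nho + 1L):length(pairs)]
    tr <- pairs[seq_len(length(pairs) - nho)]

    params <- head_flat_params(model$head)
    warmup <- ceiling(0.02 * steps)
    st <- list()
    loss_hist <- numeric(steps)
    init <- head_loss_grads(tr, model$head, config$head, with_grads = FALSE)
    ho_init <- head_loss_grads(ho, model$head, config$head, with_grads = FALSE)
    cur <- model$head
    for (s in seq_len(steps)) {
      lg <- head_loss_grads(tr, cur, config$head, with_grads = TRUE)
      loss_hist[s] <- lg$loss$total
      eta <- lr_schedule(s - 1L, lr, warmup, steps - warmup)
      upd <- adamw_step(params, lg$grads, st, eta,
                        weight_decay = config$train$weight_decay)
      params <- upd$params; st <- upd$state
      cur <- head_unflat_params(cur, params)
    }
    model$head <- cur
    fin <- head_loss_grads(tr, cur, config$head, with_grads = FALSE)
    ho_fin <- head_loss_grads(ho, cur, config$head, with_grads = FALSE)
    list(model = model, loss_history = loss_hist,
         loss_init = init$loss$total, loss_final = fin$loss$total,
         holdout_init = ho_init$loss$total, holdout_final = ho_fin$loss$total)
  })
}

#' Save / load model checkpoints
#'
#' Checkpoints are RDS files of the full weight list; a round trip
#' reproduces bit-identical forward outputs.
#' @param model a `mot_model`.
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  structure(readRDS(path), class = "mot_model")
}
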