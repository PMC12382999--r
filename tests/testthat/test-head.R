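# Detection-tracking head: branch activations, peak decoding, displacement,
# affinity, Hungarian matching, confidence fusion and losses.

test_that("detection head respects activation ranges and degenerate weights", {
  set.seed(12)
  h <- 6L
  p <- init_head(h)
  grid <- array(rnorm(8 * 8 * h), dim = c(8, 8, h))
  out <- detection_head(grid, p)
  expect_true(all(out$heatmap > 0 & out$heatmap < 1))
  expect_true(all(out$offsets > -1 & out$offsets < 1))
  expect_identical(dim(out$heatmap), c(8L, 8L))
  expect_identical(dim(out$boxes)[3], 4L)
  # zero weights: sigma(0) = 0.5, tanh(0) = 0
  pz <- p
  for (k in c("heat1", "heat2", "box1", "box2", "off1", "off2")) {
    pz[[k]]$W[] <- 0; pz[[k]]$b[] <- 0
  }
  oz <- detection_head(grid, pz)
  expect_equal(oz$heatmap, matrix(0.5, 8, 8), tolerance = 1e-12)
  expect_equal(max(abs(oz$offsets)), 0, tolerance = 1e-12)
})

test_that("decode_detections extracts thresholded ranked peaks", {
  hm <- matrix(0.5, 10, 10)
  bx <- array(0, dim = c(10, 10, 4)); of <- array(0, dim = c(10, 10, 2))
  expect_identical(nrow(decode_detections(hm, bx, of, 4L, 0.6, 10L)), 0L)

  hm2 <- matrix(0.1, 16, 16)
  g <- exp(-(outer((0:15 - 12)^2, (0:15 - 10)^2, "+")) / 8)  # peak y=12 x=10
  hm2 <- pmax(hm2, 0.9 * g)
  bx2 <- array(0, dim = c(16, 16, 4)); bx2[, , 3] <- 5; bx2[, , 4] <- 6
  of2 <- array(0, dim = c(16, 16, 2))
  det <- decode_detections(hm2, bx2, of2, 4L, 0.3, 10L)
  expect_identical(nrow(det), 1L)
  expect_identical(c(det$gx, det$gy), c(10L, 12L))
  expect_equal(det$cx, 10 * 4 + 1.5)          # stride mapping, zero offset
  expect_equal(c(det$w, det$h), c(5, 6))

  hm3 <- matrix(0.1, 16, 16)
  hm3[5, 5] <- 0.9; hm3[10, 12] <- 0.8
  det3 <- decode_detections(hm3, bx2, of2, 4L, 0.3, 1L)
  expect_identical(nrow(det3), 1L)
  expect_identical(c(det3$gx, det3$gy), c(4L, 4L))    # the higher peak
})

test_that("displacement MLP is the documented affine map", {
  set.seed(13)
  h <- 5L
  p <- init_head(h)
  p$disp1$W[] <- 0; p$disp1$b[] <- 0
  p$disp2$W[] <- 0; p$disp2$b <- c(1, -2)
  d <- predict_displacement(matrix(rnorm(3 * h), 3, h), p)
  expect_equal(d, matrix(c(1, -2), 3, 2, byrow = TRUE), tolerance = 1e-12)
  # position update arithmetic
  expect_equal(c(5, 5) + d[1, ], c(6, 3))
  expect_error(predict_displacement(matrix(0, 2, h + 1L), p), "width")
})

test_that("affinity network matches hand-computed dense evaluation", {
  set.seed(14)
  h <- 3L
  p0 <- list(l1 = list(W = matrix(0, 4 * h, 2), b = c(0, 0)),
             l2 = list(W = matrix(0, 2, 1), b = 0))
  U <- matrix(rnorm(2 * h), 2, h); V <- matrix(rnorm(2 * h), 2, h)
  a0 <- affinity(U, V, p0)
  expect_equal(a0$A, matrix(0.5, 2, 2), tolerance = 1e-12)

  pr <- list(l1 = list(W = matrix(rnorm(4 * h * 5), 4 * h, 5), b = rnorm(5)),
             l2 = list(W = matrix(rnorm(5), 5, 1), b = rnorm(1)))
  got <- affinity(U, V, pr)
  for (i in 1:2) for (j in 1:2) {
    f <- c(U[i, ], V[j, ], U[i, ] * V[j, ], abs(U[i, ] - V[j, ]))
    s <- sum(pmax(as.vector(f %*% pr$l1$W) + pr$l1$b, 0) * pr$l2$W[, 1]) +
      pr$l2$b
    expect_equal(got$s[i, j], s, tolerance = 1e-9)
    expect_equal(got$A[i, j], 1 / (1 + exp(-s)), tolerance = 1e-9)
  }
  expect_error(affinity(U, V[, 1:2], pr), "widths")
})

test_that("matching is Hungarian-optimal and partitions indices", {
  A <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  ms <- match_detections(A, 0.3)
  expect_equal(ms$pairs[, "det"], c(1, 2), ignore_attr = TRUE)
  expect_equal(ms$pairs[, "track"], c(1, 2), ignore_attr = TRUE)

  ms2 <- match_detections(matrix(0.1, 3, 2), 0.3)
  expect_identical(nrow(ms2$pairs), 0L)
  expect_identical(ms2$unmatched_det, 1:3)
  expect_identical(ms2$unmatched_track, 1:2)

  set.seed(15)
  for (t in 1:200) {
    n <- sample(2:7, 1)
    A <- matrix(runif(n * n), n, n)
    ms <- match_detections(A, accept_thresh = 0)
    tot <- sum(A[ms$pairs])
    pm <- all_perms(n)
    best <- max(apply(pm, 1, function(p) sum(A[cbind(1:n, p)])))
    expect_equal(tot, best, tolerance = 1e-9)
  }
  # partition fuzz, rectangular with threshold
  for (t in 1:50) {
    nd <- sample(0:6, 1); nt <- sample(0:6, 1)
    A <- matrix(runif(nd * nt), nd, nt)
    ms <- match_detections(A, 0.5)
    expect_setequal(c(ms$pairs[, 1], ms$unmatched_det), seq_len(nd))
    expect_setequal(c(ms$pairs[, 2], ms$unmatched_track), seq_len(nt))
    expect_identical(anyDuplicated(ms$pairs[, 1]), 0L)
    expect_identical(anyDuplicated(ms$pairs[, 2]), 0L)
  }
})

test_that("confidence fusion closed forms and monotonicity", {
  expect_equal(fuse_confidence(0.8, 0, 0), 0.8 * 0.5, tolerance = 1e-9)
  expect_equal(fuse_confidence(0.8, 1, 1),
               0.8 / (1 + exp(-2 * (2 / (2 + 1e-6)))), tolerance = 1e-9)
  expect_equal(fuse_confidence(0.8, 1, 1), 0.8 * 0.8808, tolerance = 1e-3)
  expect_equal(fuse_confidence(0.6, 0, 1), 0.6 * 0.5, tolerance = 1e-6)
  set.seed(16)
  for (i in 1:20) {
    s <- runif(1); ca <- runif(1); cm <- runif(1); d <- runif(1, 0, 0.2)
    expect_gte(fuse_confidence(s, min(ca + d, 1), cm), fuse_confidence(s, ca, cm))
    expect_gte(fuse_confidence(s, ca, min(cm + d, 1)), fuse_confidence(s, ca, cm))
    expect_gte(fuse_confidence(min(s + d, 1), ca, cm), fuse_confidence(s, ca, cm))
  }
})

test_that("loss bundle behaves at its boundary cases", {
  set.seed(17)
  boxes <- rbind(c(10, 12, 6, 6), c(30, 8, 5, 7))
  tg <- render_targets(boxes, 16L, 16L, 4L)
  pred <- list(heatmap = pmin(pmax(tg$heatmap, 1e-6), 1 - 1e-6),
               boxes = tg$boxes, offsets = tg$offsets,
               disp_boxes = boxes, true_boxes = boxes,
               affinity = matrix(c(0.999, 0.001, 0.001, 0.999), 2),
               true_boxes = boxes)
  pred$true_boxes <- boxes
  lb <- compute_losses(pred, c(tg, list(match = diag(2))))
  expect_equal(lb$L_bs, 0)
  expect_equal(lb$L_r, 0)
  expect_equal(lb$L_td, 0)
  expect_lt(lb$L_match, 0.01)
  expect_equal(lb$total, lb$L_cf + lb$L_bs + lb$L_r + lb$L_td + lb$L_match)

  # random inputs: all terms nonnegative
  rp <- list(heatmap = matrix(runif(256, 0.01, 0.99), 16),
             boxes = array(rnorm(16 * 16 * 4), c(16, 16, 4)),
             offsets = array(runif(16 * 16 * 2, -0.9, 0.9), c(16, 16, 2)),
             disp_boxes = rbind(c(0, 0, 4, 4)), true_boxes = rbind(c(10, 10, 4, 4)),
             affinity = matrix(runif(4, 0.1, 0.9), 2))
  lr <- compute_losses(rp, c(tg, list(match = diag(2))))
  expect_true(all(unlist(lr[c("L_cf", "L_bs", "L_r", "L_td", "L_match")]) >= 0))
  expect_equal(lr$L_td, 1)   # disjoint boxes: IoU 0 -> loss 1
  expect_error(compute_losses(list(heatmap = matrix(0.5, 4, 4)),
                              list(heatmap = matrix(0, 8, 8))), "shapes")
})

test_that("analytic head gradients agree with finite differences", {
  set.seed(18)
  h <- 4L
  p <- init_head(h)
  grid <- array(rnorm(6 * 6 * h, sd = 0.5), dim = c(6, 6, h))
  tg <- render_targets(rbind(c(4, 6, 6, 6), c(14, 14, 5, 5)), 6L, 6L, 4L)
  pair <- list(grid_a = grid, grid_m = grid * 0.5, target = tg,
               U = matrix(rnorm(2 * h), 2, h), V = matrix(rnorm(2 * h), 2, h),
               match_lab = diag(2),
               prev_boxes = rbind(c(3, 5, 6, 6), c(13, 13, 5, 5)),
               cur_boxes = rbind(c(4, 6, 6, 6), c(14, 14, 5, 5)))
  cfg_head <- default_config()$head

  lg <- spacemot:::head_loss_grads(list(pair), p, cfg_head)
  flat <- spacemot:::head_flat_params(p)
  eps <- 1e-5
  for (k in names(lg$grads)) {
    for (ix in seq_len(min(length(flat[[k]]), 4L))) {
      fp <- flat; fp[[k]][ix] <- fp[[k]][ix] + eps
      fm <- flat; fm[[k]][ix] <- fm[[k]][ix] - eps
      lp <- spacemot:::head_loss_grads(list(pair),
        spacemot:::head_unflat_params(p, fp), cfg_head, with_grads = FALSE)
      lm <- spacemot:::head_loss_grads(list(pair),
        spacemot:::head_unflat_params(p, fm), cfg_head, with_grads = FALSE)
      num <- (lp$loss$total - lm$loss$total) / (2 * eps)
      expect_equal(lg$grads[[k]][ix], num, tolerance = 1e-4,
                   label = paste("grad", k, ix))
    }
  }
})
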