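# Heterogeneous graph attention: typed attention algebra, encoder structure,
# deformable decoding, and gradient flow.

toy_query <- function(mat, W = 2L, H = NULL) {
  n <- nrow(mat)
  if (is.null(H)) H <- n / W
  structure(list(queries = mat,
                 coords = cbind(x = rep(seq_len(W) - 1L, times = H),
                                y = rep(seq_len(H) - 1L, each = W)),
                 H = H, W = W, modality = "appearance", stage = 1L),
            class = "query_matrix")
}

test_that("build_graph validates blocks and accepts zero memory", {
  set.seed(3)
  Da <- toy_query(matrix(rnorm(8), 4, 2))
  Dm <- toy_query(matrix(rnorm(8), 4, 2))
  g <- build_graph(Da, Dm)               # first frame: zero memory
  expect_true(all(g$T_a == 0))
  expect_error(build_graph(toy_query(matrix(0, 0, 2), W = 0L, H = 0L), Dm),
               "empty")
  expect_error(build_graph(Da, toy_query(matrix(rnorm(12), 4, 3))), "widths")
  expect_error(build_graph(Da, Dm, T_a = matrix(0, 2, 5)), "width")
})

test_that("temporal attention matches softmax algebra and brute force", {
  set.seed(4)
  h <- 3L
  p <- list(q = diag(h), k = diag(h), v = diag(h))
  Q <- matrix(rnorm(2 * h), 2, h)
  # single key: weight exactly 1
  K1 <- matrix(rnorm(h), 1, h)
  out1 <- temporal_attention(Q, K1, K1, p)
  expect_equal(attr(out1, "weights"), matrix(1, 2, 1), tolerance = 1e-12)
  # identical keys: uniform weights
  K2 <- matrix(rep(K1, each = 4), 4, h)
  out2 <- temporal_attention(Q, K2, K2, p)
  expect_equal(attr(out2, "weights"), matrix(0.25, 2, 4), tolerance = 1e-12)
  # 2-token case against a direct dense evaluation
  pr <- list(q = matrix(rnorm(h * h), h), k = matrix(rnorm(h * h), h),
             v = matrix(rnorm(h * h), h))
  K <- matrix(rnorm(2 * h), 2, h)
  V <- matrix(rnorm(2 * h), 2, h)
  got <- temporal_attention(Q, K, V, pr)
  logits <- (Q %*% pr$q) %*% t(K %*% pr$k) / sqrt(h)
  att <- exp(logits) / rowSums(exp(logits))
  expect_equal(unclass(got), att %*% (V %*% pr$v),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(rowSums(attr(got, "weights")), c(1, 1), tolerance = 1e-6)
})

test_that("spatial attention bias behaves and reduces to temporal", {
  set.seed(5)
  h <- 3L
  pr <- list(q = matrix(rnorm(h * h), h), k = matrix(rnorm(h * h), h),
             v = matrix(rnorm(h * h), h))
  phi0 <- list(l1 = list(W = matrix(0, 2, 16), b = rep(0, 16)),
               l2 = list(W = matrix(0, 16, 1), b = 0))
  Q <- matrix(rnorm(3 * h), 3, h)
  co <- cbind(c(0, 1, 2), c(0, 0, 1))
  sp <- spatial_attention(Q, Q, Q, co, co, pr, phi0)
  tp <- temporal_attention(Q, Q, Q, pr)
  expect_equal(unclass(sp), unclass(tp), tolerance = 1e-12, ignore_attr = TRUE)

  # shift invariance of the learned bias term
  phi <- spacemot:::with_seed(8, list(l1 = spacemot:::linear_init(2L, 16L),
                                      l2 = spacemot:::linear_init(16L, 1L)))
  b1 <- position_bias(co, co, phi)
  b2 <- position_bias(co + 7.5, co + 7.5, phi)
  expect_equal(b1, b2, tolerance = 1e-12)

  # overwhelming bias on one neighbor -> its weight approaches 1
  phi_big <- phi0
  phi_big$l1$W[1, 1] <- 1; phi_big$l1$b[1] <- 0
  phi_big$l2$W[1, 1] <- 100   # bias = 100 * relu(dx)
  co2 <- cbind(c(0, 1), c(0, 0))
  sp2 <- spatial_attention(Q[1:2, ], Q[1:2, ], Q[1:2, ], co2, co2, pr, phi_big)
  w <- attr(sp2, "weights")
  expect_gt(w[2, 1], 1 - 1e-9)   # query 2 sees dx=+1 toward key 1
})

test_that("heterogeneous attention sums per-modality attention", {
  set.seed(6)
  h <- 3L
  pr <- list(q = matrix(rnorm(h * h), h), k = matrix(rnorm(h * h), h),
             v = matrix(rnorm(h * h), h))
  Q <- matrix(rnorm(2 * h), 2, h)
  Ka <- matrix(rnorm(2 * h), 2, h); Va <- matrix(rnorm(2 * h), 2, h)
  # identical modalities: output is twice the single-modality output
  both <- heterogeneous_attention(Q, list(Ka, Ka), list(Va, Va), pr)
  one <- temporal_attention(Q, Ka, Va, pr)
  expect_equal(both, 2 * unclass(one), tolerance = 1e-9, ignore_attr = TRUE)
  # zero values: zero output
  z <- heterogeneous_attention(Q, list(Ka, Ka), list(Va * 0, Va * 0), pr)
  expect_equal(z, matrix(0, 2, h), tolerance = 1e-12)
  # 2-modality 2-token brute force
  Km <- matrix(rnorm(2 * h), 2, h); Vm <- matrix(rnorm(2 * h), 2, h)
  got <- heterogeneous_attention(Q, list(Ka, Km), list(Va, Vm), pr)
  ref <- matrix(0, 2, h)
  for (blk in list(list(Ka, Va), list(Km, Vm))) {
    lg <- (Q %*% pr$q) %*% t(blk[[1]] %*% pr$k) / sqrt(h)
    ref <- ref + (exp(lg) / rowSums(exp(lg))) %*% (blk[[2]] %*% pr$v)
  }
  expect_equal(got, ref, tolerance = 1e-6)
})

test_that("encode is depth-0 identity, composes the three ops, and is
           permutation-equivariant", {
  set.seed(7)
  h <- 4L
  params <- init_mhgn(h, modifyList(default_config()$mhgn, list(depth = 1L)))
  Da <- toy_query(matrix(rnorm(4 * h), 4, h))
  Dm <- toy_query(matrix(rnorm(4 * h), 4, h))
  Tm <- matrix(rnorm(2 * h), 2, h)
  g <- build_graph(Da, Dm, Tm, Tm)

  f0 <- mhgn_encode(g, params, depth = 0L)
  expect_identical(f0$D_a, g$D_a)
  expect_identical(f0$T_a, g$T_a)

  f1 <- mhgn_encode(g, params, depth = 1L)
  expect_identical(dim(f1$D_a), dim(g$D_a))
  expect_identical(dim(f1$T_m), dim(g$T_m))
  expect_true(all(is.finite(f1$D_a)))

  # manual composition of one round
  ln <- spacemot:::layer_norm
  dw <- function(x) { attr(x, "weights") <- NULL; x }
  Da1 <- ln(g$D_a + dw(temporal_attention(g$D_a, g$T_a, g$T_a, params$temporal$a)))
  Dm1 <- ln(g$D_m + dw(temporal_attention(g$D_m, g$T_m, g$T_m, params$temporal$m)))
  Q <- rbind(Da1, Dm1); co <- rbind(g$coords, g$coords)
  S <- dw(spatial_attention(Q, Q, Q, co, co, params$spatial, params$phi))
  Da2 <- ln(Da1 + S[1:4, ]); Dm2 <- ln(Dm1 + S[5:8, ])
  KV <- list(a = Da2, m = Dm2)
  Da3 <- ln(Da2 + heterogeneous_attention(Da2, KV, KV, params$hetero))
  expect_equal(f1$D_a, Da3, tolerance = 1e-9)

  # permutation equivariance of detection tokens
  perm <- c(3L, 1L, 4L, 2L)
  Dap <- Da; Dap$queries <- Da$queries[perm, ]; Dap$coords <- Da$coords[perm, ]
  Dmp <- Dm; Dmp$queries <- Dm$queries[perm, ]; Dmp$coords <- Dm$coords[perm, ]
  gp <- build_graph(Dap, Dmp, Tm, Tm)
  fp <- mhgn_encode(gp, params, depth = 1L)
  expect_equal(fp$D_a, f1$D_a[perm, ], tolerance = 1e-9)
  expect_equal(fp$D_m, f1$D_m[perm, ], tolerance = 1e-9)
})

test_that("zero memory with bias-free values contributes no temporal update", {
  set.seed(8)
  h <- 4L
  params <- init_mhgn(h)
  Tz <- matrix(0, 3, h)
  D <- matrix(rnorm(4 * h), 4, h)
  upd <- temporal_attention(D, Tz, Tz, params$temporal$a)
  expect_equal(unclass(upd), matrix(0, 4, h),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("deformable decoding equals a naive bilinear oracle", {
  set.seed(9)
  h <- 3L
  naive_bilinear <- function(feat, H, W, x, y) {
    x <- min(max(x, 0), W - 1); y <- min(max(y, 0), H - 1)
    x0 <- floor(x); y0 <- floor(y)
    x1 <- min(x0 + 1, W - 1); y1 <- min(y0 + 1, H - 1)
    fx <- x - x0; fy <- y - y0
    out <- numeric(ncol(feat))
    for (c2 in seq_len(ncol(feat))) {
      f00 <- feat[y0 * W + x0 + 1, c2]; f01 <- feat[y0 * W + x1 + 1, c2]
      f10 <- feat[y1 * W + x0 + 1, c2]; f11 <- feat[y1 * W + x1 + 1, c2]
      out[c2] <- (1 - fy) * ((1 - fx) * f00 + fx * f01) +
                 fy * ((1 - fx) * f10 + fx * f11)
    }
    out
  }
  dp <- list(heads = list(diag(h)),
             offset = list(W = matrix(0, h, 2), b = numeric(2)),
             weight = list(W = matrix(0, h, 1), b = 0),
             M = 1L, K = 1L)
  for (i in 1:50) {
    H <- sample(2:5, 1); W <- sample(2:5, 1)
    feat <- matrix(rnorm(H * W * h), H * W, h)
    q <- matrix(rnorm(h), 1, h)
    ref <- matrix(runif(2, -0.2, 1.2), 1)   # includes out-of-bounds clamping
    got <- deformable_decode(q, list(feat = feat, H = H, W = W), dp, ref)
    want <- naive_bilinear(feat, H, W,
                           min(max(ref[1], 0), 1) * (W - 1),
                           min(max(ref[2], 0), 1) * (H - 1))
    expect_equal(as.vector(got), want, tolerance = 1e-6)
  }
  # reference point on a grid node returns that node's feature
  feat <- matrix(rnorm(4 * h), 4, h)
  got <- deformable_decode(matrix(rnorm(h), 1), list(feat = feat, H = 2L, W = 2L),
                           dp, matrix(c(1, 0), 1))
  expect_equal(as.vector(got), feat[2, ], tolerance = 1e-12)
})

test_that("all live MHGN parameters receive gradients (finite differences)", {
  set.seed(10)
  h <- 4L
  params <- init_mhgn(h, modifyList(default_config()$mhgn,
                                    list(depth = 1L, heads = 2L)))
  # nonzero offsets/weights so every deformable path is active
  params$deform$offset$W[] <- rnorm(length(params$deform$offset$W), sd = 0.3)
  params$deform$offset$b[] <- rnorm(length(params$deform$offset$b), sd = 0.3)
  Da <- toy_query(matrix(rnorm(4 * h), 4, h))
  Dm <- toy_query(matrix(rnorm(4 * h), 4, h))
  Tm <- matrix(rnorm(2 * h), 2, h)
  ref <- matrix(runif(4), 2, 2)
  wfix <- matrix(rnorm(4 * h), 4, h)

  loss_fn <- function(p) {
    f <- mhgn_encode(build_graph(Da, Dm, Tm, Tm), p, depth = 1L)
    dec <- deformable_decode(f$T_a, list(feat = f$D_a, H = 2L, W = 2L),
                             p$deform, ref)
    sum(f$D_a * wfix) + sum(sin(dec))
  }
  paths <- list(
    c("temporal", "a", "q"), c("temporal", "a", "k"), c("temporal", "a", "v"),
    c("temporal", "m", "q"), c("temporal", "m", "k"), c("temporal", "m", "v"),
    c("spatial", "q"), c("spatial", "k"), c("spatial", "v"),
    c("phi", "l1", "W"), c("phi", "l1", "b"), c("phi", "l2", "W"),
    c("hetero", "q"), c("hetero", "k"), c("hetero", "v"),
    c("deform", "offset", "W"), c("deform", "offset", "b"),
    c("deform", "weight", "W"), c("deform", "weight", "b"))
  eps <- 1e-5
  for (pth in paths) {
    arr <- params[[pth]]
    # probe a few entries of each parameter array
    probe <- seq_len(min(length(arr), 3L))
    any_nonzero <- FALSE
    for (ix in probe) {
      pp <- params; pm <- params
      pp[[pth]][ix] <- pp[[pth]][ix] + eps
      pm[[pth]][ix] <- pm[[pth]][ix] - eps
      gr <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
      if (abs(gr) > 1e-7) any_nonzero <- TRUE
    }
    expect_true(any_nonzero, label = paste("grad flow:", paste(pth, collapse = "$")))
  }
  for (m in 1:2) {
    pp <- params; pm <- params
    pp$deform$heads[[m]][1, 1] <- pp$deform$heads[[m]][1, 1] + eps
    pm$deform$heads[[m]][1, 1] <- pm$deform$heads[[m]][1, 1] - eps
    expect_gt(abs(loss_fn(pp) - loss_fn(pm)) / (2 * eps), 1e-7)
  }
})
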