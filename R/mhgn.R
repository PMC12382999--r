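# Multi-modal heterogeneous graph network. Nodes are four typed blocks --
# appearance / motion detection queries of the current frame and appearance /
# motion trajectory memory of the previous frame (zero at sequence start) --
# and edges are typed: temporal (detection <-> memory within a modality),
# spatial (within-frame, with a learned relative-position bias), and
# heterogeneous (cross-modal detection <-> detection). The graph is realized
# as typed attention over index sets, not via a graph library.

#' Initialize MHGN attention parameters
#'
#' @param hidden query width h.
#' @param cfg mhgn config sub-list.
#' @return parameter list with per-edge-type projections, the relative
#'   position bias MLP `phi` and deformable-decoder weights.
#' @export
init_mhgn <- function(hidden, cfg = default_config()$mhgn) {
  h <- as.integer(hidden)
  # bias-free projections: the typed-attention formulas carry none, and key/
  # query biases would be gradient-dead under softmax shift invariance
  proj <- function() list(q = rand_mat(h, h), k = rand_mat(h, h),
                          v = rand_mat(h, h))
  M <- as.integer(cfg$heads); K <- 4L
  off <- linear_init(h, 2L * M * K); off$W[] <- 0; off$b[] <- 0  # start at plain sampling
  structure(list(
    temporal = list(a = proj(), m = proj()),
    spatial = proj(),
    phi = list(l1 = linear_init(2L, 16L), l2 = linear_init(16L, 1L)),
    hetero = proj(),
    deform = list(heads = lapply(seq_len(M), function(i) rand_mat(h, h, 1 / (M * sqrt(h)))),
                  offset = off, weight = linear_init(h, M * K),
                  M = M, K = K),
    hidden = h, depth = as.integer(cfg$depth),
    k_spatial = as.integer(cfg$k_spatial),
    spatial_cross = isTRUE(cfg$spatial_cross),
    mem_momentum = cfg$mem_momentum
  ), class = "mhgn_params")
}

#' Build the heterogeneous graph over queries and trajectory memory
#'
#' @param D_a,D_m `query_matrix` objects (appearance / motion detection
#'   queries) sharing the hidden width and grid.
#' @param T_a,T_m trajectory memory matrices (N_t x h), or `NULL` at sequence
#'   start (replaced by a single all-zero token).
#' @param k_spatial spatial neighborhood size; full attention when the token
#'   count is at most 64.
#' @return object of class `hetero_graph`.
#' @export
build_graph <- function(D_a, D_m, T_a = NULL, T_m = NULL, k_spatial = 8L) {
  h <- ncol(D_a$queries)
  if (nrow(D_a$queries) == 0L || nrow(D_m$queries) == 0L) {
    stop("empty detection query set", call. = FALSE)
  }
  if (ncol(D_m$queries) != h) stop("query widths differ", call. = FALSE)
  if (is.null(T_a)) T_a <- matrix(0, 1L, h)
  if (is.null(T_m)) T_m <- matrix(0, 1L, h)
  if (ncol(T_a) != h || ncol(T_m) != h) {
    stop("memory width differs from query width", call. = FALSE)
  }
  n <- nrow(D_a$queries)
  neighbors <- NULL
  if (n > 64L) {
    co <- D_a$coords
    neighbors <- t(vapply(seq_len(n), function(i) {
      d2 <- (co[, 1] - co[i, 1])^2 + (co[, 2] - co[i, 2])^2
      order(d2)[seq_len(min(k_spatial, n))]
    }, integer(min(k_spatial, n))))
  }
  structure(list(D_a = D_a$queries, D_m = D_m$queries, T_a = T_a, T_m = T_m,
                 coords = D_a$coords, H = D_a$H, W = D_a$W,
                 neighbors = neighbors),
            class = "hetero_graph")
}

#' Temporal (intra-modality) attention
#'
#' Plain scaled dot-product attention with modality-specific projections:
#' `softmax(Q Wq (K Wk)' / sqrt(d)) V Wv`.
#' @param Q,K,V token matrices (queries; keys/values from the same modality's
#'   other temporal block).
#' @param p projection triple (`q`, `k`, `v` linear maps).
#' @return refined block, with the attention matrix in attribute `"weights"`.
#' @export
temporal_attention <- function(Q, K, V, p) {
  d <- ncol(Q)
  qm <- Q %*% p$q; km <- K %*% p$k; vm <- V %*% p$v
  att <- softmax_rows(qm %*% t(km) / sqrt(d))
  structure(att %*% vm, weights = att)
}

#' Relative-position bias
#'
#' Two-layer perceptron on the pairwise offsets (dx, dy); depends only on
#' coordinate differences, hence invariant to a global shift of all tokens.
#' @param coords_q,coords_k matrices of 0-based (x, y) token coordinates.
#' @param phi the bias MLP parameters.
#' @return `nrow(coords_q)` x `nrow(coords_k)` bias matrix.
#' @export
position_bias <- function(coords_q, coords_k, phi) {
  nq <- nrow(coords_q); nk <- nrow(coords_k)
  dx <- outer(coords_q[, 1], coords_k[, 1], "-")
  dy <- outer(coords_q[, 2], coords_k[, 2], "-")
  z <- cbind(as.vector(dx), as.vector(dy))
  # no bias on the output layer: a per-row constant would vanish in softmax
  b <- relu(linear_fwd(z, phi$l1)) %*% phi$l2$W
  matrix(b, nq, nk)
}

#' Spatial attention with relative-position bias
#'
#' Adds `phi(dx, dy)` to the attention logits; when a `neighbors` index
#' matrix is given, softmax runs over each query's spatial neighborhood only.
#' With a zero bias and no neighborhood restriction this reduces exactly to
#' [temporal_attention()]'s formula.
#' @inheritParams temporal_attention
#' @param coords_q,coords_k 0-based token coordinates.
#' @param neighbors optional N_q x k matrix of key indices per query.
#' @export
spatial_attention <- function(Q, K, V, coords_q, coords_k, p, phi,
                              neighbors = NULL) {
  d <- ncol(Q)
  qm <- Q %*% p$q; km <- K %*% p$k; vm <- V %*% p$v
  logits <- qm %*% t(km) / sqrt(d) + position_bias(coords_q, coords_k, phi)
  if (!is.null(neighbors)) {
    mask <- matrix(-Inf, nrow(logits), ncol(logits))
    for (i in seq_len(nrow(neighbors))) mask[i, neighbors[i, ]] <- 0
    logits <- logits + mask
  }
  att <- softmax_rows(logits)
  structure(att %*% vm, weights = att)
}

#' Heterogeneous (cross-node-type) attention
#'
#' Unnormalized sum over modalities of per-modality softmax attention with a
#' shared query projection: `sum_m softmax(Q Wq (K_m Wk)'/sqrt(d)) V_m Wv`.
#' @param Q query block.
#' @param K_list,V_list named lists of per-modality key/value blocks.
#' @param p shared projection triple.
#' @export
heterogeneous_attention <- function(Q, K_list, V_list, p) {
  d <- ncol(Q)
  qm <- Q %*% p$q
  out <- matrix(0, nrow(Q), ncol(Q))
  for (m in seq_along(K_list)) {
    km <- K_list[[m]] %*% p$k
    vm <- V_list[[m]] %*% p$v
    out <- out + softmax_rows(qm %*% t(km) / sqrt(d)) %*% vm
  }
  out
}

#' Run the MHGN encoder over a graph
#'
#' `depth` rounds of temporal, then spatial, then heterogeneous attention
#' (narrative order of the three edge types), each followed by a residual
#' connection and layer normalization. Temporal attention refines detection
#' blocks from the same-modality memory and vice versa; spatial attention
#' runs over detection tokens (cross-modality when `spatial_cross`);
#' heterogeneous attention exchanges information between the two detection
#' modalities. `depth = 0` is the identity.
#'
#' @param graph from [build_graph()].
#' @param params from [init_mhgn()].
#' @param depth override of `params$depth`.
#' @return object of class `fused_queries`: list with refined `D_a`, `D_m`
#'   and memory blocks `T_a`, `T_m`, plus grid geometry.
#' @export
mhgn_encode <- function(graph, params, depth = params$depth) {
  dw <- function(x) { attr(x, "weights") <- NULL; x }   # drop diagnostic attrs
  D_a <- graph$D_a; D_m <- graph$D_m; T_a <- graph$T_a; T_m <- graph$T_m
  for (r in seq_len(depth)) {
    # temporal edges (within modality, detection <-> memory)
    Da2 <- layer_norm(D_a + dw(temporal_attention(D_a, T_a, T_a, params$temporal$a)))
    Dm2 <- layer_norm(D_m + dw(temporal_attention(D_m, T_m, T_m, params$temporal$m)))
    T_a <- layer_norm(T_a + dw(temporal_attention(T_a, D_a, D_a, params$temporal$a)))
    T_m <- layer_norm(T_m + dw(temporal_attention(T_m, D_m, D_m, params$temporal$m)))
    D_a <- Da2; D_m <- Dm2
    # spatial edges over detection tokens
    if (params$spatial_cross) {
      Q <- rbind(D_a, D_m)
      co <- rbind(graph$coords, graph$coords)
      nb <- if (is.null(graph$neighbors)) NULL else {
        n <- nrow(graph$coords)
        rbind(cbind(graph$neighbors, graph$neighbors + n),
              cbind(graph$neighbors, graph$neighbors + n))
      }
      S <- dw(spatial_attention(Q, Q, Q, co, co, params$spatial, params$phi, nb))
      n <- nrow(D_a)
      D_a <- layer_norm(D_a + S[seq_len(n), , drop = FALSE])
      D_m <- layer_norm(D_m + S[n + seq_len(n), , drop = FALSE])
    } else {
      D_a <- layer_norm(D_a + dw(spatial_attention(D_a, D_a, D_a, graph$coords,
        graph$coords, params$spatial, params$phi, graph$neighbors)))
      D_m <- layer_norm(D_m + dw(spatial_attention(D_m, D_m, D_m, graph$coords,
        graph$coords, params$spatial, params$phi, graph$neighbors)))
    }
    # heterogeneous edges between the two detection modalities
    KV <- list(a = D_a, m = D_m)
    Da3 <- layer_norm(D_a + heterogeneous_attention(D_a, KV, KV, params$hetero))
    Dm3 <- layer_norm(D_m + heterogeneous_attention(D_m, KV, KV, params$hetero))
    D_a <- Da3; D_m <- Dm3
  }
  structure(list(D_a = D_a, D_m = D_m, T_a = T_a, T_m = T_m,
                 coords = graph$coords, H = graph$H, W = graph$W),
            class = "fused_queries")
}

#' Deformable attention decoding of track queries
#'
#' For each query and each of `M` heads, samples the fused feature grid by
#' bilinear interpolation at the query's reference point plus learned
#' per-point offsets, combines the samples with softmax weights (summing to 1
#' per head) and mixes heads through per-head linear maps. Offsets are
#' predicted by a zero-initialized linear layer, so an untrained decoder is
#' plain sampling at the reference points. Out-of-bounds samples clamp to the
#' grid border.
#'
#' @param queries N x h track queries.
#' @param grid list with `feat` (row-major token matrix), `H`, `W`.
#' @param dp deformable parameters (`params$deform` from [init_mhgn()]).
#' @param ref N x 2 reference points in normalized [0, 1] coordinates
#'   (mapped to pixels as `x * (W - 1)`).
#' @return N x h decoded queries.
#' @export
deformable_decode <- function(queries, grid, dp, ref) {
  n <- nrow(queries); h <- ncol(queries)
  M <- dp$M; K <- dp$K
  offs <- linear_fwd(queries, dp$offset)           # n x (2*M*K)
  wts <- linear_fwd(queries, dp$weight)            # n x (M*K)
  out <- matrix(0, n, h)
  px0 <- ref[, 1] * (grid$W - 1)
  py0 <- ref[, 2] * (grid$H - 1)
  for (m in seq_len(M)) {
    wl <- wts[, ((m - 1L) * K + 1L):(m * K), drop = FALSE]
    wl <- softmax_rows(wl)
    acc <- matrix(0, n, h)
    for (q in seq_len(K)) {
      j <- (m - 1L) * K + q
      dx <- offs[, 2L * j - 1L]; dy <- offs[, 2L * j]
      s <- bilinear_sample_tokens(grid$feat, grid$H, grid$W, px0 + dx, py0 + dy)
      acc <- acc + wl[, q] * s
    }
    out <- out + acc %*% dp$heads[[m]]
  }
  out
}
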