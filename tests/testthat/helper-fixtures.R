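# Shared fixtures: analytic textures (exact at fractional shifts), brute-force
# enumeration helpers, oracle detector stubs, and a lazily trained tiny model
# reused across expensive tests.

# smooth periodic texture, evaluable at fractional offsets
analytic_texture <- function(h, w, sx = 0, sy = 0) {
  outer(0:(h - 1), 0:(w - 1), function(y, x) {
    xx <- x + sx; yy <- y + sy
    0.5 + 0.15 * sin(2 * pi * xx / 17 + 1) * cos(2 * pi * yy / 13) +
      0.12 * cos(2 * pi * xx / 23 - 0.4) * sin(2 * pi * yy / 19 + 2) +
      0.08 * sin(2 * pi * (xx + yy) / 11)
  })
}

interior <- function(m, k = 8L) m[(k + 1L):(nrow(m) - k), (k + 1L):(ncol(m) - k)]

all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  p <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, ifelse(p >= k, p + 1L, p))
  }))
}

# oracle detector stub: perfect GT boxes + stable per-identity embeddings
make_oracle_detector <- function(sim, hidden, emb_seed = 99L, emb_noise = 0.05) {
  n_ids <- max(sim$gt$id)
  id_emb <- spacemot:::with_seed(emb_seed,
    matrix(rnorm(n_ids * hidden), n_ids, hidden))
  function(f, frame) {
    g <- sim$gt[sim$gt$frame == f - 1L & sim$gt$visible, , drop = FALSE]
    d <- data.frame(cx = g$x + g$w / 2, cy = g$y + g$h / 2, w = g$w, h = g$h,
                    score = 0.9, c_a = 0.9, c_m = 0.9)
    e <- id_emb[g$id, , drop = FALSE]
    if (emb_noise > 0) {
      e <- e + matrix(rnorm(length(e), sd = emb_noise), nrow(e))
    }
    attr(d, "emb") <- e
    d
  }
}

gt_as_mot <- function(sim) {
  data.frame(frame = sim$gt$frame + 1L, id = sim$gt$id, x = sim$gt$x,
             y = sim$gt$y, w = sim$gt$w, h = sim$gt$h)
}

# random MOT scenario generator for metric fuzzing: jittered/dropped/relabeled
# copies of a small simulated ground truth
random_mot_scenario <- function(seed) {
  set.seed(seed)
  n_ids <- sample(2:4, 1)
  n_frames <- sample(6:10, 1)
  gt <- do.call(rbind, lapply(seq_len(n_frames), function(f) {
    data.frame(frame = f, id = seq_len(n_ids),
               x = runif(n_ids, 0, 50), y = runif(n_ids, 0, 50),
               w = runif(n_ids, 6, 10), h = runif(n_ids, 6, 10))
  }))
  pred <- gt
  pred$x <- pred$x + rnorm(nrow(pred), 0, 1)
  pred$y <- pred$y + rnorm(nrow(pred), 0, 1)
  keep <- runif(nrow(pred)) > 0.15
  pred <- pred[keep, , drop = FALSE]
  # occasional identity corruption
  flip <- runif(nrow(pred)) < 0.1
  pred$id[flip] <- sample(seq_len(n_ids + 2L), sum(flip), replace = TRUE)
  # spurious boxes
  n_fp <- rpois(1, 2)
  if (n_fp > 0) {
    pred <- rbind(pred, data.frame(
      frame = sample(seq_len(n_frames), n_fp, replace = TRUE),
      id = sample(50:60, n_fp, replace = TRUE),
      x = runif(n_fp, 0, 50), y = runif(n_fp, 0, 50),
      w = runif(n_fp, 6, 10), h = runif(n_fp, 6, 10)))
  }
  pred <- pred[!duplicated(pred[, c("frame", "id")]), , drop = FALSE]
  list(gt = gt, pred = pred)
}

# lazily trained tiny model shared between the training criterion and the
# end-to-end learned-tracker smoke test (training is the expensive part)
.trained_cache <- new.env(parent = emptyenv())

trained_fixture <- function() {
  if (is.null(.trained_cache$res)) {
    cfg <- default_config()
    # easy regime: slow well-separated agents in private cells
    sim <- simulate_arena(arena_config(width = 64L, height = 64L,
      n_agents = 4L, n_frames = 20L, speed = 0.8, impulse_rate = 0,
      turn_sd = 0.1, radius_mean = 3, cell_confine = TRUE, seed = 7L))
    .trained_cache$sim <- sim
    .trained_cache$res <- train_tiny(sim, cfg, steps = 200L)
  }
  list(sim = .trained_cache$sim, res = .trained_cache$res)
}
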