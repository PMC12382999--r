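# Independent naive reference implementations used to validate the metric
# and assignment code paths. Deliberately written with loops, brute-force
# permutation search and no shared code with the package internals.

naive_iou <- function(a, b) {
  x1 <- max(a[1], b[1]); y1 <- max(a[2], b[2])
  x2 <- min(a[1] + a[3], b[1] + b[3]); y2 <- min(a[2] + a[4], b[2] + b[4])
  iw <- max(0, x2 - x1); ih <- max(0, y2 - y1)
  inter <- iw * ih
  u <- a[3] * a[4] + b[3] * b[4] - inter
  if (u <= 0) 0 else inter / u
}

# exhaustive max-total-IoU matching among pairs above the gate
naive_best_matching <- function(iou, gate) {
  ng <- nrow(iou); np <- ncol(iou)
  if (ng == 0 || np == 0) return(rep(NA_integer_, ng))
  best <- rep(NA_integer_, ng); best_tot <- -1
  cols <- seq_len(np)
  rec <- function(i, used, cur, tot) {
    if (i > ng) {
      if (tot > best_tot + 1e-12) { best_tot <<- tot; best <<- cur }
      return()
    }
    rec(i + 1L, used, { c2 <- cur; c2[i] <- NA_integer_; c2 }, tot)
    for (j in cols) {
      if (!(j %in% used) && iou[i, j] >= gate) {
        rec(i + 1L, c(used, j), { c2 <- cur; c2[i] <- j; c2 }, tot + iou[i, j])
      }
    }
  }
  rec(1L, integer(), rep(NA_integer_, ng), 0)
  best
}

# per-frame event recount with CLEAR continuity preference
naive_clear_events <- function(gt, pred, gate = 0.5) {
  frames <- sort(unique(c(gt$frame, pred$frame)))
  prev <- list()
  fp <- 0L; fn <- 0L; idsw <- 0L; ngt <- 0L
  match_log <- list()
  for (f in frames) {
    g <- gt[gt$frame == f, , drop = FALSE]
    p <- pred[pred$frame == f, , drop = FALSE]
    ngt <- ngt + nrow(g)
    iou <- matrix(0, nrow(g), nrow(p))
    for (i in seq_len(nrow(g))) for (j in seq_len(nrow(p))) {
      iou[i, j] <- naive_iou(as.numeric(g[i, c("x", "y", "w", "h")]),
                             as.numeric(p[j, c("x", "y", "w", "h")]))
    }
    assign <- rep(NA_integer_, nrow(g))
    usedp <- integer()
    for (i in seq_len(nrow(g))) {
      pid <- prev[[as.character(g$id[i])]]
      if (!is.null(pid)) {
        j <- which(p$id == pid)
        if (length(j) == 1L && iou[i, j] >= gate) {
          assign[i] <- j; usedp <- c(usedp, j)
        }
      }
    }
    restg <- which(is.na(assign)); restp <- setdiff(seq_len(nrow(p)), usedp)
    if (length(restg) && length(restp)) {
      sub <- naive_best_matching(iou[restg, restp, drop = FALSE], gate)
      for (k in seq_along(restg)) {
        if (!is.na(sub[k])) assign[restg[k]] <- restp[sub[k]]
      }
    }
    for (i in seq_len(nrow(g))) {
      key <- as.character(g$id[i])
      if (!is.na(assign[i])) {
        pid <- p$id[assign[i]]
        if (!is.null(prev[[key]]) && prev[[key]] != pid) idsw <- idsw + 1L
        prev[[key]] <- pid
        match_log[[length(match_log) + 1L]] <-
          data.frame(frame = f, gt_id = g$id[i])
      } else fn <- fn + 1L
    }
    fp <- fp + nrow(p) - sum(!is.na(assign))
  }
  ml <- if (length(match_log)) do.call(rbind, match_log) else
    data.frame(frame = integer(), gt_id = integer())
  list(fp = fp, fn = fn, idsw = idsw, ngt = ngt, matches = ml)
}

naive_mota <- function(gt, pred, gate = 0.5) {
  ev <- naive_clear_events(gt, pred, gate)
  1 - (ev$fp + ev$fn + ev$idsw) / ev$ngt
}

naive_fragments <- function(gt, pred, gate = 0.5) {
  ev <- naive_clear_events(gt, pred, gate)
  total <- 0L
  for (gid in unique(gt$id)) {
    fr <- sort(gt$frame[gt$id == gid])
    m <- fr %in% ev$matches$frame[ev$matches$gt_id == gid]
    r <- rle(m)
    if (length(r$values) >= 3L) {
      for (k in 2:(length(r$values) - 1L)) {
        if (!r$values[k] && r$values[k - 1L] && any(r$values[(k + 1L):length(r$values)])) {
          total <- total + 1L
        }
      }
    }
    total <- total + 0L
  }
  total
}

naive_mt_ml <- function(gt, pred, gate = 0.5) {
  ev <- naive_clear_events(gt, pred, gate)
  mt <- 0L; ml <- 0L
  for (gid in unique(gt$id)) {
    fr <- sort(gt$frame[gt$id == gid])
    span <- max(fr) - min(fr) + 1
    cov <- sum(fr %in% ev$matches$frame[ev$matches$gt_id == gid]) / span
    if (cov >= 0.8) mt <- mt + 1L
    if (cov <= 0.2) ml <- ml + 1L
  }
  list(MT = mt, ML = ml)
}

# brute-force IDF1: exhaustive injective mapping of GT identities into
# predicted identities maximizing the total per-frame overlap count
naive_idf1 <- function(gt, pred, gate = 0.5) {
  gids <- sort(unique(gt$id)); pids <- sort(unique(pred$id))
  C <- matrix(0, length(gids), length(pids))
  for (gi in seq_along(gids)) for (pi in seq_along(pids)) {
    g <- gt[gt$id == gids[gi], , drop = FALSE]
    p <- pred[pred$id == pids[pi], , drop = FALSE]
    for (f in intersect(g$frame, p$frame)) {
      a <- as.numeric(g[g$frame == f, c("x", "y", "w", "h")][1, ])
      b <- as.numeric(p[p$frame == f, c("x", "y", "w", "h")][1, ])
      if (naive_iou(a, b) >= gate) C[gi, pi] <- C[gi, pi] + 1L
    }
  }
  best <- 0
  rec <- function(i, used, tot) {
    if (i > length(gids)) { best <<- max(best, tot); return() }
    rec(i + 1L, used, tot)
    for (j in seq_along(pids)) {
      if (!(j %in% used)) rec(i + 1L, c(used, j), tot + C[i, j])
    }
  }
  if (length(pids)) rec(1L, integer(), 0)
  idtp <- best
  2 * idtp / (2 * idtp + (nrow(pred) - idtp) + (nrow(gt) - idtp))
}
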