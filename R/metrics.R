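# CLEAR-MOT and identity metrics. Per-frame correspondence uses IoU-gated
# Hungarian assignment with the CLEAR match-continuity convention (a pairing
# from the previous frame is kept while it stays above the gate); MOTA
# aggregates FP/FN/IDSW over GT box count; IDF1 uses a whole-sequence
# bipartite matching between GT and predicted identities.

#' Per-frame GT-to-prediction correspondence
#'
#' @param gt,pred data.frames with `frame`, `id`, `x`, `y`, `w`, `h` (same
#'   frame base in both).
#' @param iou_thresh IoU gate, default 0.5.
#' @return object of class `frame_assignment`: per-frame list with `matches`
#'   (gt_id, pred_id), `fp`, `fn`, `idsw`, plus box totals.
#' @export
assign_frames <- function(gt, pred, iou_thresh = 0.5) {
  need <- c("frame", "id", "x", "y", "w", "h")
  if (!all(need %in% names(gt)) || !all(need %in% names(pred))) {
    stop("records need columns frame,id,x,y,w,h", call. = FALSE)
  }
  frames <- sort(union(unique(gt$frame), unique(pred$frame)))
  prev <- list()   # gt_id (chr) -> pred id from its most recent match
  out <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    g <- gt[gt$frame == f, , drop = FALSE]
    p <- pred[pred$frame == f, , drop = FALSE]
    ng <- nrow(g); np <- nrow(p)
    iou <- matrix(0, ng, np)
    if (ng && np) {
      for (i in seq_len(ng)) {
        iou[i, ] <- box_iou(
          matrix(rep(as.numeric(g[i, c("x", "y", "w", "h")]), np),
                 np, 4, byrow = TRUE),
          as.matrix(p[, c("x", "y", "w", "h")]))
      }
    }
    gm <- rep(NA_integer_, ng)   # matched pred row per gt row
    # continuity: keep surviving previous pairings first
    if (ng && np) {
      for (i in seq_len(ng)) {
        pid <- prev[[as.character(g$id[i])]]
        if (!is.null(pid)) {
          j <- match(pid, p$id)
          if (!is.na(j) && iou[i, j] >= iou_thresh) gm[i] <- j
        }
      }
      usedp <- stats::na.omit(gm)
      restg <- which(is.na(gm))
      restp <- setdiff(seq_len(np), usedp)
      if (length(restg) && length(restp)) {
        sc <- iou[restg, restp, drop = FALSE]
        sc[sc < iou_thresh] <- -Inf
        as2 <- solve_assignment_max(sc)
        for (k in seq_along(restg)) {
          if (!is.na(as2[k])) gm[restg[k]] <- restp[as2[k]]
        }
      }
    }
    idsw <- 0L
    matches <- NULL
    for (i in seq_len(ng)) {
      if (!is.na(gm[i])) {
        pid <- p$id[gm[i]]
        key <- as.character(g$id[i])
        if (!is.null(prev[[key]]) && prev[[key]] != pid) idsw <- idsw + 1L
        prev[[key]] <- pid
        matches <- rbind(matches, data.frame(gt_id = g$id[i], pred_id = pid))
      }
    }
    out[[fi]] <- list(
      frame = f,
      matches = if (is.null(matches))
        data.frame(gt_id = integer(), pred_id = integer()) else matches,
      fp = np - sum(!is.na(gm)),
      fn = ng - sum(!is.na(gm)),
      idsw = idsw,
      n_gt = ng
    )
  }
  structure(list(frames = out, gt = gt, pred = pred,
                 iou_thresh = iou_thresh), class = "frame_assignment")
}

#' Multiple object tracking accuracy
#'
#' `MOTA = 1 - (sum FP + sum FN + sum IDSW) / sum GT`; may be negative,
#' at most 1.
#' @param assignments a `frame_assignment`.
#' @return scalar MOTA.
#' @export
mota <- function(assignments) {
  tot <- mot_event_totals(assignments)
  if (tot$gt == 0L) stop("MOTA undefined: no ground-truth boxes", call. = FALSE)
  1 - (tot$fp + tot$fn + tot$idsw) / tot$gt
}

#' Event totals of a frame assignment
#' @param assignments a `frame_assignment`.
#' @return list with `fp`, `fn`, `idsw`, `gt` totals.
#' @export
mot_event_totals <- function(assignments) {
  list(
    fp = sum(vapply(assignments$frames, `[[`, 0L, "fp")),
    fn = sum(vapply(assignments$frames, `[[`, 0L, "fn")),
    idsw = sum(vapply(assignments$frames, `[[`, 0L, "idsw")),
    gt = sum(vapply(assignments$frames, `[[`, 0L, "n_gt"))
  )
}

#' Identity F1 score
#'
#' Whole-sequence bipartite matching between GT and predicted identities
#' maximizing the count of frames where a paired GT/prediction box overlap
#' (IoU at or above the gate); then
#' `IDF1 = 2 IDTP / (2 IDTP + IDFP + IDFN)`.
#' @param gt,pred MOT record data.frames.
#' @param iou_thresh IoU gate.
#' @return list with `IDF1`, `IDTP`, `IDFP`, `IDFN`.
#' @export
idf1 <- function(gt, pred, iou_thresh = 0.5) {
  if (nrow(gt) == 0L) stop("IDF1 undefined: no ground-truth boxes", call. = FALSE)
  gids <- sort(unique(gt$id)); pids <- sort(unique(pred$id))
  C <- matrix(0, length(gids), length(pids))
  if (length(pids)) {
    for (gi in seq_along(gids)) {
      g <- gt[gt$id == gids[gi], , drop = FALSE]
      for (pi in seq_along(pids)) {
        p <- pred[pred$id == pids[pi], , drop = FALSE]
        common <- intersect(g$frame, p$frame)
        if (!length(common)) next
        gi2 <- match(common, g$frame); pi2 <- match(common, p$frame)
        ious <- box_iou(as.matrix(g[gi2, c("x", "y", "w", "h")]),
                        as.matrix(p[pi2, c("x", "y", "w", "h")]))
        C[gi, pi] <- sum(ious >= iou_thresh)
      }
    }
  }
  idtp <- 0
  if (length(pids)) {
    as1 <- solve_assignment_max(C)
    for (i in seq_along(as1)) if (!is.na(as1[i])) idtp <- idtp + C[i, as1[i]]
  }
  idfp <- nrow(pred) - idtp
  idfn <- nrow(gt) - idtp
  list(IDF1 = 2 * idtp / (2 * idtp + idfp + idfn),
       IDTP = idtp, IDFP = idfp, IDFN = idfn)
}

per_gt_match_series <- function(assignments) {
  gt <- assignments$gt
  gids <- sort(unique(gt$id))
  lapply(stats::setNames(gids, gids), function(gid) {
    fr <- sort(gt$frame[gt$id == gid])
    matched <- vapply(fr, function(f) {
      fa <- assignments$frames[[match(f, vapply(assignments$frames, `[[`, 0, "frame"))]]
      gid %in% fa$matches$gt_id
    }, logical(1))
    list(frames = fr, matched = matched)
  })
}

#' Trajectory fragmentation count
#'
#' Counts, over GT trajectories, the transitions from matched to unmatched
#' that are later followed by a re-match (each interruption once).
#' @param assignments a `frame_assignment`.
#' @return integer fragment count.
#' @export
fragments <- function(assignments) {
  series <- per_gt_match_series(assignments)
  total <- 0L
  for (s in series) {
    m <- s$matched
    inside <- FALSE; frag <- 0L
    seen_match <- FALSE
    for (v in m) {
      if (v) {
        if (inside && seen_match) frag <- frag + 1L
        inside <- FALSE; seen_match <- TRUE
      } else if (seen_match) inside <- TRUE
    }
    total <- total + frag
  }
  total
}

#' Mostly-tracked / mostly-lost trajectory counts
#'
#' A GT trajectory's lifespan is the inclusive frame range between its first
#' and last appearance; MT requires coverage of at least 80% of it, ML at
#' most 20% (both bounds inclusive).
#' @param assignments a `frame_assignment`.
#' @return list with `MT`, `ML`.
#' @export
mt_ml <- function(assignments) {
  series <- per_gt_match_series(assignments)
  mt <- 0L; ml <- 0L
  for (s in series) {
    span <- max(s$frames) - min(s$frames) + 1
    cov <- sum(s$matched) / span
    if (cov >= 0.8) mt <- mt + 1L
    if (cov <= 0.2) ml <- ml + 1L
  }
  list(MT = mt, ML = ml)
}

#' Full metrics report
#'
#' @param gt,pred MOT record data.frames (matching frame base).
#' @param iou_thresh IoU gate, default 0.5.
#' @return object of class `metrics_report` with MOTA, IDF1, Frag, IDSW,
#'   MT, ML and all event totals.
#' @export
evaluate_tracking <- function(gt, pred, iou_thresh = 0.5) {
  asg <- assign_frames(gt, pred, iou_thresh)
  tot <- mot_event_totals(asg)
  idr <- idf1(gt, pred, iou_thresh)
  mm <- mt_ml(asg)
  structure(list(
    MOTA = mota(asg), IDF1 = idr$IDF1, Frag = fragments(asg),
    IDSW = tot$idsw, MT = mm$MT, ML = mm$ML,
    IDTP = idr$IDTP, IDFP = idr$IDFP, IDFN = idr$IDFN,
    FP = tot$fp, FN = tot$fn, GT = tot$gt
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("MOTA %.4f | IDF1 %.4f | Frag %d | IDSW %d | MT %d | ML %d\n",
              x$MOTA, x$IDF1, x$Frag, x$IDSW, x$MT, x$ML))
  cat(sprintf("FP %d FN %d GT %d | IDTP %g IDFP %g IDFN %g\n",
              x$FP, x$FN, x$GT, x$IDTP, x$IDFP, x$IDFN))
  invisible(x)
}
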