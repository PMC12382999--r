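# Frame-by-frame tracker: motion decoupling -> dual-stream backbone -> graph
# fusion -> detection head -> confidence fusion -> gated affinity matching
# against active tracks -> cross-modal re-detection against recently lost
# tracks -> lifecycle update. A detector stub may replace the learned trunk
# for oracle tests and ablations.

#' Initialize all model weights
#'
#' @param config full configuration (see [default_config()]).
#' @param in_channels appearance input channels (1 grayscale, 3 RGB).
#' @return object of class `mot_model` with backbone, projection, graph and
#'   head parameters. Deterministic given `config$seed`.
#' @export
init_model <- function(config = default_config(), in_channels = 1L) {
  with_seed(config$seed, {
    h <- config$model$hidden
    backbone_a <- init_backbone(in_channels, config$model)
    backbone_m <- if (isTRUE(config$model$share_backbone) && in_channels == 2L) {
      backbone_a
    } else init_backbone(2L, config$model)
    structure(list(
      backbone_a = backbone_a,
      backbone_m = backbone_m,
      proj_a = init_projection(backbone_a, h, config$model$pe_bands),
      proj_m = init_projection(backbone_m, h, config$model$pe_bands),
      mhgn = init_mhgn(h, config$mhgn),
      head = init_head(h),
      hidden = h, in_channels = in_channels,
      config = config
    ), class = "mot_model")
  })
}

#' Create an empty tracker state
#' @return list holding the track table and frame counter.
#' @export
tracker_state <- function() {
  list(tracks = list(), next_id = 1L, frame = 0L, retired_ids = integer())
}

new_track <- function(id, frame, det, emb) {
  list(id = id, state = "active", tsu = 0L, age = 1L,
       cx = det$cx, cy = det$cy, w = det$w, h = det$h,
       vx = 0, vy = 0, score = det$fused,
       emb = emb, mem = emb,
       history = data.frame(frame = frame, x = det$cx - det$w / 2,
                            y = det$cy - det$h / 2, w = det$w, h = det$h,
                            score = det$fused))
}

# run the learned trunk on a frame pair, returning decoded detections with
# embeddings, the fused token grid and updated track memories
forward_trunk <- function(frame_prev, frame_cur, model, state, config) {
  tcfg <- config$tracker
  if (isTRUE(tcfg$use_motion) && !identical(frame_prev, frame_cur)) {
    mf <- motion_features(frame_prev, frame_cur, config$motion)
    raster <- mf$raster
  } else {
    raster <- array(0, dim = c(dim(frame_cur), 2L))
  }
  stage <- min(config$model$stages_used)
  pyr_a <- extract_pyramid(frame_cur, model$backbone_a, "appearance")
  pyr_m <- extract_pyramid(raster, model$backbone_m, "motion")
  D_a <- flatten_project(pyr_a, stage, model$proj_a)
  D_m <- flatten_project(pyr_m, stage, model$proj_m)
  act <- Filter(function(t) t$state != "terminated", state$tracks)
  T_mem <- if (length(act)) {
    do.call(rbind, lapply(act, `[[`, "mem"))
  } else NULL
  if (isTRUE(tcfg$use_mhgn)) {
    # memory_in_graph = FALSE keeps feature extraction consistent with the
    # memory-free protocol of train_tiny (desk-scale trained trunks)
    T_g <- if (isTRUE(config$mhgn$memory_in_graph)) T_mem else NULL
    g <- build_graph(D_a, D_m, T_g, T_g, config$mhgn$k_spatial)
    fused <- mhgn_encode(g, model$mhgn)
  } else {
    fused <- list(D_a = D_a$queries, D_m = D_m$queries,
                  T_a = T_mem, T_m = T_mem,
                  coords = D_a$coords, H = D_a$H, W = D_a$W)
  }
  grid_a <- queries_to_grid(fused$D_a, D_a$H, D_a$W)
  grid_m <- queries_to_grid(fused$D_m, D_m$H, D_m$W)
  out_a <- detection_head(grid_a, model$head)
  out_m <- detection_head(grid_m, model$head)
  # peaks come from the appearance-stream head (already cross-modal after
  # graph fusion); the motion-stream head contributes its confidence c_m,
  # scored downstream by the harmonic confidence fusion
  heat <- out_a$heatmap
  stride <- STAGE_RATIOS[stage]
  det <- decode_detections(heat, out_a$boxes, out_a$offsets, stride,
                           config$head$score_thresh, config$head$max_det,
                           c_a = out_a$heatmap, c_m = out_m$heatmap)
  mix <- (fused$D_a + fused$D_m) / 2
  emb <- if (nrow(det)) mix[det$token, , drop = FALSE] else
    matrix(0, 0L, ncol(mix))
  # refresh persistent memories through the deformable decoder
  if (length(act)) {
    W_px <- ncol(frame_cur); H_px <- nrow(frame_cur)
    ref <- cbind(
      pmin(pmax(vapply(act, `[[`, 0, "cx") / max(W_px - 1, 1), 0), 1),
      pmin(pmax(vapply(act, `[[`, 0, "cy") / max(H_px - 1, 1), 0), 1))
    dec <- deformable_decode(do.call(rbind, lapply(act, `[[`, "mem")),
      list(feat = mix, H = D_a$H, W = D_a$W), model$mhgn$deform, ref)
    mom <- model$mhgn$mem_momentum
    for (k in seq_along(act)) {
      act[[k]]$mem <- mom * act[[k]]$mem + (1 - mom) * dec[k, ]
    }
    for (k in seq_along(act)) {
      state$tracks[[which(vapply(state$tracks, `[[`, 0L, "id") == act[[k]]$id)]]$mem <- act[[k]]$mem
    }
  }
  det$fused <- fuse_confidence(det$score, det$c_a, det$c_m,
                               config$head$fusion_gamma, config$head$fusion_eps)
  list(det = det, emb = emb, state = state)
}

predicted_center <- function(tr, model, use_mlp = TRUE) {
  if (use_mlp && !is.null(tr$mem)) {
    d <- predict_displacement(matrix(tr$mem, 1L), model$head)
    # blend learned displacement with the observed velocity
    c(tr$cx + tr$vx + d[1, 1], tr$cy + tr$vy + d[1, 2])
  } else {
    c(tr$cx + tr$vx, tr$cy + tr$vy)
  }
}

#' Re-detection of lost tracks
#'
#' Scores unmatched detections against recently lost (inactive) tracks with
#' the learned affinity network, gated by motion consistency: a detection is
#' a candidate only within `gate_radius` of the track's extrapolated position
#' `p + v * time_since_update`. A Hungarian pass over the gated matrix
#' revives pairs above `redet_thresh` under the old identity.
#'
#' @param lost list of inactive tracks.
#' @param det_emb embeddings of unmatched detections (N x h).
#' @param det_centers N x 2 matrix of detection centers.
#' @param model the `mot_model`.
#' @param config full config.
#' @return integer matrix of (detection index, lost-track index) revivals.
#' @export
redetect <- function(lost, det_emb, det_centers, model, config) {
  if (!length(lost) || !nrow(det_emb)) return(matrix(integer(), 0L, 2L))
  V <- do.call(rbind, lapply(lost, `[[`, "emb"))
  aff <- affinity(det_emb, V, model$head$affinity)$A
  gate <- config$tracker$gate_radius
  for (j in seq_along(lost)) {
    tr <- lost[[j]]
    pred <- c(tr$cx + tr$vx * (tr$tsu + 1L), tr$cy + tr$vy * (tr$tsu + 1L))
    d <- sqrt((det_centers[, 1] - pred[1])^2 + (det_centers[, 2] - pred[2])^2)
    aff[d > gate + tr$tsu, j] <- -Inf
  }
  ms <- match_detections(aff, config$tracker$redet_thresh)
  ms$pairs
}

#' Advance the tracker by one frame
#'
#' Runs the full pipeline on the (previous, current) frame pair, associates
#' decoded detections with active tracks (gated learned affinity + Hungarian),
#' offers leftovers to lost tracks via [redetect()] when enabled, and updates
#' the track lifecycle: matched tracks refresh, unmatched active tracks turn
#' inactive, inactive tracks past `max_inactive_frames` terminate, unmatched
#' detections above `spawn_score_thresh` spawn new identities.
#'
#' @param frame_prev,frame_cur same-shape frames (matrices in [0,1]).
#' @param model a `mot_model`.
#' @param state tracker state from [tracker_state()] or a previous step.
#' @param config full config (defaults to the model's).
#' @param detector optional stub `function(frame_index, frame)` returning a
#'   detection data.frame (`cx`,`cy`,`w`,`h`,`score`,`c_a`,`c_m`) with an
#'   `"emb"` attribute; replaces the learned trunk entirely.
#' @return list with `records` (this frame's output rows) and `state`.
#' @export
tracker_step <- function(frame_prev, frame_cur, model, state,
                         config = model$config, detector = NULL) {
  if (!identical(dim(frame_prev), dim(frame_cur))) {
    stop("frame shape mismatch", call. = FALSE)
  }
  tcfg <- config$tracker
  state$frame <- state$frame + 1L
  f <- state$frame

  if (is.null(detector)) {
    tr <- forward_trunk(frame_prev, frame_cur, model, state, config)
    det <- tr$det; emb <- tr$emb; state <- tr$state
    use_mlp <- TRUE
  } else {
    det <- detector(f, frame_cur)
    emb <- attr(det, "emb")
    if (is.null(emb)) emb <- matrix(0, nrow(det), model$hidden)
    if (is.null(det$fused)) {
      det$fused <- fuse_confidence(det$score, det$c_a %||% det$score,
                                   det$c_m %||% det$score,
                                   config$head$fusion_gamma,
                                   config$head$fusion_eps)
    }
    use_mlp <- FALSE
  }

  idx_active <- which(vapply(state$tracks, function(t) t$state == "active", TRUE))
  idx_lost <- which(vapply(state$tracks, function(t) t$state == "inactive", TRUE))
  nd <- nrow(det)

  matched_det <- integer(0); matched_trk <- integer(0)
  if (nd && length(idx_active)) {
    V <- do.call(rbind, lapply(state$tracks[idx_active], `[[`, "emb"))
    aff <- affinity(emb, V, model$head$affinity)$A
    for (j in seq_along(idx_active)) {
      p <- predicted_center(state$tracks[[idx_active[j]]], model, use_mlp)
      d <- sqrt((det$cx - p[1])^2 + (det$cy - p[2])^2)
      aff[d > tcfg$gate_radius, j] <- -Inf
    }
    ms <- match_detections(aff, tcfg$match_thresh)
    matched_det <- ms$pairs[, 1]
    matched_trk <- idx_active[ms$pairs[, 2]]
  }

  # re-detection of lost identities
  un_det <- setdiff(seq_len(nd), matched_det)
  if (isTRUE(tcfg$use_redet) && length(un_det) && length(idx_lost)) {
    lost <- state$tracks[idx_lost]
    keep <- which(vapply(lost, `[[`, 0L, "tsu") <= tcfg$max_inactive_frames)
    if (length(keep)) {
      pairs <- redetect(lost[keep], emb[un_det, , drop = FALSE],
                        cbind(det$cx, det$cy)[un_det, , drop = FALSE],
                        model, config)
      if (nrow(pairs)) {
        matched_det <- c(matched_det, un_det[pairs[, 1]])
        matched_trk <- c(matched_trk, idx_lost[keep[pairs[, 2]]])
      }
    }
  }

  # lifecycle updates
  for (k in seq_along(matched_det)) {
    di <- matched_det[k]; ti <- matched_trk[k]
    tr <- state$tracks[[ti]]
    dt <- max(tr$tsu + 1L, 1L)
    tr$vx <- (det$cx[di] - tr$cx) / dt
    tr$vy <- (det$cy[di] - tr$cy) / dt
    tr$cx <- det$cx[di]; tr$cy <- det$cy[di]
    tr$w <- det$w[di]; tr$h <- det$h[di]
    tr$score <- det$fused[di]
    tr$state <- "active"; tr$tsu <- 0L; tr$age <- tr$age + 1L
    mom <- config$mhgn$mem_momentum
    tr$emb <- mom * tr$emb + (1 - mom) * emb[di, ]
    tr$history <- rbind(tr$history, data.frame(
      frame = f, x = det$cx[di] - det$w[di] / 2, y = det$cy[di] - det$h[di] / 2,
      w = det$w[di], h = det$h[di], score = det$fused[di]))
    state$tracks[[ti]] <- tr
  }
  for (ti in seq_along(state$tracks)) {
    tr <- state$tracks[[ti]]
    if (tr$state == "terminated" || ti %in% matched_trk) next
    tr$tsu <- tr$tsu + 1L
    if (tr$state == "active") tr$state <- "inactive"
    if (tr$tsu > tcfg$max_inactive_frames) {
      tr$state <- "terminated"
      state$retired_ids <- c(state$retired_ids, tr$id)
    }
    state$tracks[[ti]] <- tr
  }
  un_det <- setdiff(seq_len(nd), matched_det)
  for (di in un_det) {
    if (det$fused[di] >= tcfg$spawn_score_thresh) {
      tr <- new_track(state$next_id, f, det[di, ], emb[di, ])
      state$next_id <- state$next_id + 1L
      state$tracks <- c(state$tracks, list(tr))
    }
  }

  act <- Filter(function(t) t$state == "active", state$tracks)
  records <- if (length(act)) data.frame(
    frame = f,
    id = vapply(act, `[[`, 0L, "id"),
    x = vapply(act, function(t) t$cx - t$w / 2, 0),
    y = vapply(act, function(t) t$cy - t$h / 2, 0),
    w = vapply(act, `[[`, 0, "w"),
    h = vapply(act, `[[`, 0, "h"),
    conf = vapply(act, `[[`, 0, "score")
  ) else data.frame(frame = integer(), id = integer(), x = numeric(),
                    y = numeric(), w = numeric(), h = numeric(),
                    conf = numeric())
  list(records = records, state = state)
}

#' Track a whole frame sequence
#'
#' @param frames list of same-shape matrices (>= 2), e.g. from
#'   [read_frames()] or `simulate_arena()$frames`.
#' @param model a `mot_model`.
#' @param config full config (defaults to the model's).
#' @param detector optional stub, see [tracker_step()].
#' @param out_path optional MOTChallenge CSV output path.
#' @return data.frame of MOT records (`frame` 1-based, `id`, `x`, `y`, `w`,
#'   `h`, `conf`), with the final state in attribute `"state"`.
#' @export
track_sequence <- function(frames, model, config = model$config,
                           detector = NULL, out_path = NULL) {
  if (length(frames) < 2L) stop("need at least 2 frames", call. = FALSE)
  state <- tracker_state()
  recs <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    prev <- frames[[max(k - 1L, 1L)]]
    st <- tracker_step(prev, frames[[k]], model, state, config, detector)
    recs[[k]] <- st$records
    state <- st$state
  }
  out <- do.call(rbind, recs)
  if (!is.null(out_path)) {
    write_mot(cbind(out, a = -1, b = -1), out_path)
  }
  attr(out, "state") <- state
  out
}
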