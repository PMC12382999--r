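# Synthetic microgravity-arena simulator. Produces grayscale frame stacks and
# MOT-style ground truth emulating the statistical regime the tracker
# targets: many visually near-identical smooth blobs, piecewise-constant
# velocities broken by Poisson-timed random impulses (sudden accelerations),
# per-frame random turns (sharp direction changes), reflective walls, frequent
# crossings/occlusions, and mild sensor noise. It deliberately does not mimic
# the appearance of any real organism.

#' Arena configuration
#'
#' @param width,height arena size in pixels (64-256 for bundled scenarios).
#' @param n_agents number of agents (>= 1).
#' @param radius_mean,radius_sd agent blob radius distribution (px).
#' @param speed base speed (px/frame).
#' @param impulse_rate per-frame probability of a random velocity impulse.
#' @param impulse_mag impulse magnitude (px/frame).
#' @param turn_sd sd of the per-frame random heading change (radians).
#' @param occlusion_iou IoU above which the later agent counts as occluded
#'   in the ground truth's visibility flag (GT records always remain).
#' @param n_frames frame count.
#' @param noise_sd sd of additive Gaussian sensor noise.
#' @param cell_confine confine each agent to its own grid cell (guarantees
#'   non-overlap; used by the `easy_separated` scenario).
#' @param seed RNG seed; fully determines the output.
#' @return object of class `arena_config`.
#' @export
arena_config <- function(width = 96L, height = 96L, n_agents = 6L,
                         radius_mean = 2.5, radius_sd = 0.3, speed = 1.5,
                         impulse_rate = 0.1, impulse_mag = 2.0, turn_sd = 0.2,
                         occlusion_iou = 0.8, n_frames = 40L, noise_sd = 0.01,
                         cell_confine = FALSE, seed = 0L) {
  stopifnot(n_agents >= 1L, impulse_rate >= 0, impulse_rate <= 1)
  cfg <- list(width = as.integer(width), height = as.integer(height),
              n_agents = as.integer(n_agents), radius_mean = radius_mean,
              radius_sd = radius_sd, speed = speed,
              impulse_rate = impulse_rate, impulse_mag = impulse_mag,
              turn_sd = turn_sd, occlusion_iou = occlusion_iou,
              n_frames = as.integer(n_frames), noise_sd = noise_sd,
              cell_confine = cell_confine, seed = as.integer(seed))
  if (4 * radius_mean > min(width, height)) {
    stop("agents too large for arena", call. = FALSE)
  }
  class(cfg) <- "arena_config"
  cfg
}

#' Curated scenario configurations
#'
#' `easy_separated`: 5 slow agents confined to disjoint cells (no overlap
#' ever). `crossing_pair`: two agents on a head-on collision course with a
#' guaranteed full occlusion at mid-sequence. `dense_occlusion`: 12 agents in
#' a crowded arena. `erratic`: high impulse rate and magnitude.
#' @param name scenario name.
#' @param seed RNG seed.
#' @return an `arena_config`.
#' @export
scenario <- function(name, seed = 0L) {
  switch(name,
    easy_separated = arena_config(width = 128L, height = 128L, n_agents = 5L,
      speed = 0.8, impulse_rate = 0, impulse_mag = 0, turn_sd = 0.1,
      n_frames = 30L, cell_confine = TRUE, seed = seed),
    crossing_pair = {
      # symmetric half-step pass: |dx| = speed at frames t_meet, t_meet + 1,
      # giving exactly two full-occlusion frames with radius 3, speed 0.5
      cfg <- arena_config(width = 96L, height = 64L, n_agents = 2L,
        speed = 0.5, impulse_rate = 0, impulse_mag = 0, turn_sd = 0,
        radius_mean = 3.0, radius_sd = 0, n_frames = 30L, seed = seed)
      cfg$scripted <- "crossing"
      cfg
    },
    dense_occlusion = arena_config(width = 128L, height = 128L, n_agents = 12L,
      speed = 1.5, impulse_rate = 0.15, impulse_mag = 2.0, n_frames = 40L,
      seed = seed),
    erratic = arena_config(width = 96L, height = 96L, n_agents = 4L,
      speed = 2.0, impulse_rate = 0.4, impulse_mag = 3.0, turn_sd = 0.5,
      n_frames = 40L, seed = seed),
    stop("unknown scenario: ", name, call. = FALSE)
  )
}

render_frame <- function(px, py, r, gain, W, H, noise_sd) {
  img <- matrix(0, H, W)
  xs <- 0:(W - 1); ys <- 0:(H - 1)
  for (i in seq_along(px)) {
    s2 <- 2 * (r[i] / 1.5)^2
    gx <- exp(-(xs - px[i])^2 / s2)
    gy <- exp(-(ys - py[i])^2 / s2)
    img <- img + gain[i] * outer(gy, gx)
  }
  img <- img + matrix(stats::rnorm(H * W, sd = noise_sd), H, W)
  pmin(pmax(img, 0), 1)
}

#' Simulate a synthetic arena sequence
#'
#' Agents follow piecewise-constant-velocity motion with per-frame random
#' heading turns and Bernoulli-timed velocity impulses, reflecting off the
#' arena walls (or their private cell walls under `cell_confine`). Frames are
#' sums of Gaussian blobs with per-agent intensity gain plus sensor noise.
#' Bit-reproducible given `config$seed`.
#'
#' @param config an [arena_config()].
#' @return object of class `sim_sequence`: list with `frames` (list of
#'   matrices in [0,1]), `gt` (data.frame `frame` 0-based, `id`, `x`, `y`,
#'   `w`, `h`, `visible`), `traj` (continuous centers), `n_impulses`
#'   (per-agent impulse counts), `config`.
#' @export
simulate_arena <- function(config) {
  stopifnot(inherits(config, "arena_config"))
  with_seed(config$seed, {
    W <- config$width; H <- config$height; n <- config$n_agents
    r <- pmax(1, stats::rnorm(n, config$radius_mean, config$radius_sd))
    gain <- stats::runif(n, 0.75, 0.95)
    scripted <- identical(config$scripted %||% "", "crossing")
    if (scripted) {
      # head-on pass along the horizontal midline; meet at mid-sequence
      midx <- (W - 1) / 2; midy <- (H - 1) / 2
      t_meet <- config$n_frames %/% 2L
      s <- config$speed
      px <- c(midx - s * t_meet - s / 2, midx + s * t_meet + s / 2)
      py <- c(midy, midy)
      vx <- c(s, -s); vy <- c(0, 0)
    } else if (config$cell_confine) {
      k <- ceiling(sqrt(n))
      cw <- W / k; ch <- H / ceiling(n / k)
      cell <- lapply(seq_len(n) - 1L, function(i) {
        cx0 <- (i %% k) * cw; cy0 <- (i %/% k) * ch
        c(cx0 + 2 * r[i + 1] + 1, cx0 + cw - 2 * r[i + 1] - 1,
          cy0 + 2 * r[i + 1] + 1, cy0 + ch - 2 * r[i + 1] - 1)
      })
      px <- vapply(cell, function(cl) mean(cl[1:2]), 0)
      py <- vapply(cell, function(cl) mean(cl[3:4]), 0)
      ang <- stats::runif(n, 0, 2 * pi)
      vx <- config$speed * cos(ang); vy <- config$speed * sin(ang)
    } else {
      px <- stats::runif(n, 2 * r + 1, W - 2 * r - 2)
      py <- stats::runif(n, 2 * r + 1, H - 2 * r - 2)
      ang <- stats::runif(n, 0, 2 * pi)
      vx <- config$speed * cos(ang); vy <- config$speed * sin(ang)
    }
    max_speed <- config$speed + config$impulse_mag
    frames <- vector("list", config$n_frames)
    gt <- vector("list", config$n_frames)
    traj <- vector("list", config$n_frames)
    n_impulses <- integer(n)

    for (t in seq_len(config$n_frames) - 1L) {
      frames[[t + 1L]] <- render_frame(px, py, r, gain, W, H, config$noise_sd)
      bw <- 2 * r; bh <- 2 * r
      bx <- px - r; by <- py - r
      visible <- rep(TRUE, n)
      if (n > 1L) {
        for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
          iou <- box_iou(c(bx[i], by[i], bw[i], bh[i]),
                         c(bx[j], by[j], bw[j], bh[j]))
          if (iou > config$occlusion_iou) visible[j] <- FALSE
        }
      }
      gt[[t + 1L]] <- data.frame(frame = t, id = seq_len(n), x = bx, y = by,
                                 w = bw, h = bh, visible = visible)
      traj[[t + 1L]] <- data.frame(frame = t, id = seq_len(n), cx = px, cy = py)
      if (t + 1L == config$n_frames) break
      if (!scripted) {
        if (config$turn_sd > 0) {
          dth <- stats::rnorm(n, 0, config$turn_sd)
          vx2 <- vx * cos(dth) - vy * sin(dth)
          vy <- vx * sin(dth) + vy * cos(dth)
          vx <- vx2
        }
        if (config$impulse_rate > 0) {
          hit <- stats::runif(n) < config$impulse_rate
          n_impulses <- n_impulses + hit
          if (any(hit)) {
            ia <- stats::runif(sum(hit), 0, 2 * pi)
            vx[hit] <- vx[hit] + config$impulse_mag * cos(ia)
            vy[hit] <- vy[hit] + config$impulse_mag * sin(ia)
          }
        }
        sp <- sqrt(vx^2 + vy^2)
        over <- sp > max_speed
        if (any(over)) {
          vx[over] <- vx[over] * max_speed / sp[over]
          vy[over] <- vy[over] * max_speed / sp[over]
        }
      }
      px <- px + vx; py <- py + vy
      # wall (or cell-wall) reflection
      for (i in seq_len(n)) {
        lims <- if (config$cell_confine) cell[[i]] else
          c(r[i], W - 1 - r[i], r[i], H - 1 - r[i])
        if (px[i] < lims[1]) { px[i] <- 2 * lims[1] - px[i]; vx[i] <- -vx[i] }
        if (px[i] > lims[2]) { px[i] <- 2 * lims[2] - px[i]; vx[i] <- -vx[i] }
        if (py[i] < lims[3]) { py[i] <- 2 * lims[3] - py[i]; vy[i] <- -vy[i] }
        if (py[i] > lims[4]) { py[i] <- 2 * lims[4] - py[i]; vy[i] <- -vy[i] }
      }
    }
    structure(list(frames = frames, gt = do.call(rbind, gt),
                   traj = do.call(rbind, traj), n_impulses = n_impulses,
                   config = config), class = "sim_sequence")
  })
}

#' Write a simulated sequence to disk
#'
#' Frames go to `<dir>/img/frame_%06d.pgm` (plain-text PGM, lexicographic
#' order) and ground truth to `<dir>/gt.txt` in the MOTChallenge dialect
#' (`frame,id,x,y,w,h,1,1,1`, 1-based frame ids), plus `config.txt` recording
#' the generating configuration.
#' @param seq a `sim_sequence`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_mot_gt <- function(seq, dir) {
  img_dir <- file.path(dir, "img")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(seq$frames)) {
    write_pgm(seq$frames[[i]], file.path(img_dir, sprintf("frame_%06d.pgm", i)))
  }
  g <- seq$gt
  recs <- data.frame(frame = g$frame + 1L, id = g$id, x = g$x, y = g$y,
                     w = g$w, h = g$h, conf = 1, a = 1, b = 1)
  write_mot(recs, file.path(dir, "gt.txt"))
  cfgl <- seq$config[!vapply(seq$config, is.null, TRUE)]
  writeLines(paste0(names(cfgl), ": ", vapply(cfgl, function(v)
    paste(format(v, digits = 10), collapse = ","), "")),
    file.path(dir, "config.txt"))
  invisible(dir)
}
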