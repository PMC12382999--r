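# Run configuration: nested defaults for every module, a minimal YAML-subset
# reader, and precedence handling defaults < file < explicit overrides.

#' Default configuration for every module
#'
#' Training defaults (optimizer, learning rate, schedule, augmentation,
#' input resolution) follow the architecture's full-scale training recipe; `train$steps` and the tiny model profile
#' (`model$widths`, `mhgn$depth`) are deliberately small so the full pipeline
#' runs on a single CPU in seconds.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    seed = 42L,
    motion = list(
      window = 5L, alpha = 0.1, beta = 0.01, lambda = 1.0, ridge = 1e-4,
      iters = 5L, stat_window = 31L, k1 = 1.0, k2 = 2.5, min_rho = 1e-6
    ),
    model = list(
      hidden = 16L,
      depths = c(1L, 1L, 1L, 1L),
      widths = c(8L, 16L, 32L, 64L),
      pe_bands = 8L,
      stages_used = c(1L, 2L, 3L, 4L),
      share_backbone = FALSE,
      input_size = 512L
    ),
    mhgn = list(
      depth = 1L, heads = 8L, k_spatial = 8L, mem_momentum = 0.9,
      spatial_cross = TRUE, memory_in_graph = TRUE
    ),
    head = list(
      focal_alpha = 2.0, focal_beta = 4.0,
      fusion_gamma = 2.0, fusion_eps = 1e-6,
      motion_noise_std = 0.0,
      score_thresh = 0.3, max_det = 100L
    ),
    tracker = list(
      match_thresh = 0.3, redet_thresh = 0.3,
      max_inactive_frames = 30L, spawn_score_thresh = 0.4,
      gate_radius = 16.0,
      use_motion = TRUE, use_mhgn = TRUE, use_redet = TRUE
    ),
    train = list(
      optimizer = "adamw", lr = 2e-4, batch_size = 16L, epochs = 300L,
      schedule = "cosine", warmup_steps = 1000L, weight_decay = 0.05,
      aug_flip = TRUE, aug_rot_deg = 30.0, steps = 200L
    ),
    metrics = list(iou_thresh = 0.5)
  )
}

merge_validate <- function(base, upd, path = "") {
  for (k in names(upd)) {
    full <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(base)) {
      stop("unknown config key: ", full, call. = FALSE)
    }
    if (is.list(base[[k]])) {
      if (!is.list(upd[[k]])) stop("config key ", full, " must be a section", call. = FALSE)
      base[[k]] <- merge_validate(base[[k]], upd[[k]], full)
    } else {
      v <- upd[[k]]
      if (is.numeric(base[[k]]) && !is.numeric(v)) {
        stop("config key ", full, " must be numeric", call. = FALSE)
      }
      if (is.logical(base[[k]]) && !is.logical(v)) {
        stop("config key ", full, " must be logical", call. = FALSE)
      }
      if (is.integer(base[[k]]) && is.numeric(v)) v <- as.integer(round(v))
      base[[k]] <- v
    }
  }
  base
}

parse_scalar <- function(s) {
  s <- trimws(s)
  if (s %in% c("true", "True", "TRUE", "yes")) return(TRUE)
  if (s %in% c("false", "False", "FALSE", "no")) return(FALSE)
  if (grepl("^\\[.*\\]$", s)) {
    parts <- strsplit(gsub("^\\[|\\]$", "", s), ",")[[1]]
    return(vapply(parts, function(p) as.numeric(trimws(p)), numeric(1)))
  }
  n <- suppressWarnings(as.numeric(s))
  if (!is.na(n)) return(n)
  gsub('^"|"$', "", s)
}

#' Read a configuration file and merge with defaults
#'
#' The file is a flat YAML subset: top-level `section:` lines followed by
#' indented `key: value` pairs (numbers, true/false, quoted strings, and
#' `[a, b, c]` numeric lists). Precedence is defaults < file < `overrides`
#' (a named list with dotted keys such as `"tracker.match_thresh"`).
#' Unknown keys are rejected by name.
#'
#' @param path config file path, or `NULL` for pure defaults.
#' @param overrides named list of dotted-key overrides.
#' @return validated nested config list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    upd <- list()
    section <- NULL
    for (ln in lines) {
      if (grepl("^\\S.*:\\s*$", ln)) {
        section <- sub(":\\s*$", "", ln)
        upd[[section]] <- upd[[section]] %||% list()
      } else if (grepl("^\\s+\\S+\\s*:", ln)) {
        if (is.null(section)) stop("config entry outside a section: ", ln, call. = FALSE)
        key <- sub("^\\s*(\\S+?)\\s*:.*$", "\\1", ln)
        val <- sub("^\\s*\\S+?\\s*:\\s*", "", ln)
        upd[[section]][[key]] <- parse_scalar(val)
      } else if (grepl("^\\S+\\s*:\\s*\\S", ln)) {
        key <- sub("\\s*:.*$", "", ln)
        upd[[key]] <- parse_scalar(sub("^\\S+\\s*:\\s*", "", ln))
        section <- NULL
      } else {
        stop("unparseable config line: ", ln, call. = FALSE)
      }
    }
    cfg <- merge_validate(cfg, upd)
  }
  if (length(overrides)) {
    nested <- list()
    for (k in names(overrides)) {
      parts <- strsplit(k, ".", fixed = TRUE)[[1]]
      if (length(parts) == 1L) nested[[parts]] <- overrides[[k]]
      else {
        nested[[parts[1]]] <- nested[[parts[1]]] %||% list()
        nested[[parts[1]]][[parts[2]]] <- overrides[[k]]
      }
    }
    cfg <- merge_validate(cfg, nested)
  }
  cfg
}
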