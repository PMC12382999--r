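# File I/O: MOTChallenge CSV records and plain-text PGM frames. All output
# is UTF-8, newline-terminated, with locale-independent number formatting.

#' Read MOTChallenge CSV records
#'
#' Expects at least 7 comma-separated fields per line
#' (`frame,id,x,y,w,h,conf,...`); header lines and blank lines are skipped
#' with a warning; any other malformed line is an error naming its line
#' number. Frame and id are 1-based in the file (kept as read).
#'
#' @param path CSV path.
#' @return data.frame with columns `frame`, `id`, `x`, `y`, `w`, `h`, `conf`.
#' @export
read_mot <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    parts <- strsplit(ln, ",", fixed = TRUE)[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (any(is.na(vals))) {
      if (i == 1L || grepl("[A-Za-z]", ln)) {
        warning("skipping non-numeric line ", i, " in ", path, call. = FALSE)
        next
      }
      stop("malformed record at line ", i, " of ", path, call. = FALSE)
    }
    if (length(vals) < 7L) {
      stop("line ", i, " of ", path, " has ", length(vals),
           " fields (>= 7 required)", call. = FALSE)
    }
    out[[i]] <- vals[1:7]
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) {
    return(data.frame(frame = integer(), id = integer(), x = numeric(),
                      y = numeric(), w = numeric(), h = numeric(),
                      conf = numeric()))
  }
  m <- do.call(rbind, out)
  data.frame(frame = as.integer(m[, 1]), id = as.integer(m[, 2]),
             x = m[, 3], y = m[, 4], w = m[, 5], h = m[, 6], conf = m[, 7])
}

#' Write MOTChallenge CSV records
#'
#' Emits `frame,id,x,y,w,h,conf,-1,-1,-1` rows (filler fields from columns
#' `a`,`b` if present, else -1). Round-trips losslessly through [read_mot()].
#' @param records data.frame with at least `frame,id,x,y,w,h,conf`.
#' @param path output path.
#' @export
write_mot <- function(records, path) {
  a <- records$a %||% rep(-1, nrow(records))
  b <- records$b %||% rep(-1, nrow(records))
  fmt <- function(v) {
    s <- formatC(v, format = "fg", digits = 10, flag = "-")
    trimws(s)
  }
  lines <- sprintf("%d,%d,%s,%s,%s,%s,%s,%s,%s,-1",
                   as.integer(records$frame), as.integer(records$id),
                   fmt(records$x), fmt(records$y), fmt(records$w),
                   fmt(records$h), fmt(records$conf), fmt(a), fmt(b))
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Write a matrix as a plain-text PGM (P2) image
#'
#' Intensities in [0, 1] scale to `maxval` (255, or 65535 for the 16-bit
#' debug dumps of the motion module).
#' @param img numeric matrix in [0, 1].
#' @param path output path.
#' @param maxval 255 or 65535.
#' @export
write_pgm <- function(img, path, maxval = 255L) {
  q <- round(pmin(pmax(img, 0), 1) * maxval)
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  writeLines(apply(q, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' Read a plain-text PGM (P2) image
#' @param path PGM path.
#' @return numeric matrix in [0, 1].
#' @export
read_pgm <- function(path) {
  if (!file.exists(path)) stop("unreadable frame: ", path, call. = FALSE)
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (toks[1] != "P2") stop("not a plain PGM (P2) file: ", path, call. = FALSE)
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  maxval <- as.numeric(toks[4])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != w * h) stop("truncated PGM: ", path, call. = FALSE)
  matrix(vals, h, w, byrow = TRUE) / maxval
}

#' Read an ordered frame sequence from a directory
#'
#' Frames are the `.pgm` files of `dir` in lexicographic order.
#' @param dir directory path.
#' @return list of matrices in [0, 1].
#' @export
read_frames <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.pgm$", full.names = TRUE))
  if (!length(files)) stop("no .pgm frames in ", dir, call. = FALSE)
  lapply(files, read_pgm)
}

#' Dump motion-module debug images
#'
#' Writes the polar magnitude/angle channels and the trinary mask as 16-bit
#' PGM files, and the sparse features as a CSV (`x,y,rho,theta`).
#' @param mf result of [motion_features()].
#' @param dir output directory.
#' @export
write_motion_debug <- function(mf, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rmax <- max(mf$polar$rho, 1e-9)
  write_pgm(mf$polar$rho / rmax, file.path(dir, "rho.pgm"), 65535L)
  write_pgm((mf$polar$theta + pi) / (2 * pi), file.path(dir, "theta.pgm"), 65535L)
  write_pgm(mf$mask / 2, file.path(dir, "mask.pgm"), 65535L)
  utils::write.csv(mf$features[, c("x", "y", "rho", "theta")],
                   file.path(dir, "features.csv"), row.names = FALSE)
  invisible(dir)
}
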