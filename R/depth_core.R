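#' @useDynLib depthgait, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rnorm runif sd setNames
#' @importFrom utils read.csv write.csv
NULL

DEPTH_WIDTH <- 320L
DEPTH_HEIGHT <- 240L

#' Camera intrinsics for a depth stream
#'
#' Pinhole-model intrinsic parameters of the depth camera, used to translate
#' metric (mm) anthropometric quantities into pixel counts at a given depth.
#' Defaults are the canonical structured-light depth-camera values scaled to a
#' 320 x 240 stream; real units should override them from calibration.
#'
#' @param focal_x,focal_y focal lengths in pixels (> 0).
#' @param center_x,center_y principal point in pixel coordinates (0-based,
#'   column / row respectively), inside the frame.
#' @param width,height frame size in pixels.
#' @return An object of class `depth_intrinsics`.
#' @export
#' @examples
#' intr <- depth_intrinsics()
#' mm_to_px(100, 2856, intr)  # 10 px
depth_intrinsics <- function(focal_x = 285.6, focal_y = 285.6,
                             center_x = 159.5, center_y = 119.75,
                             width = 320L, height = 240L) {
  stopifnot(focal_x > 0, focal_y > 0,
            center_x >= 0, center_x < width,
            center_y >= 0, center_y < height)
  structure(list(focal_x = focal_x, focal_y = focal_y,
                 center_x = center_x, center_y = center_y,
                 width = as.integer(width), height = as.integer(height)),
            class = "depth_intrinsics")
}

#' @export
print.depth_intrinsics <- function(x, ...) {
  cat(sprintf("depth_intrinsics: f = (%.2f, %.2f) px, c = (%.2f, %.2f), %d x %d\n",
              x$focal_x, x$focal_y, x$center_x, x$center_y, x$width, x$height))
  invisible(x)
}

# round-half-up, the convention used for every mm -> px conversion
round_half_up <- function(x) floor(x + 0.5)

#' Convert a metric length to a pixel count at a given depth
#'
#' Pinhole relation `round(L * f / Z)`: a segment of length `length_mm` lying
#' in a fronto-parallel plane at depth `depth_mm` spans that many pixels.
#' This is how body-scale shifts stated in millimetres (e.g. the 40-mm scan
#' step or the 100-mm neck allowance) become row/column counts.
#'
#' @param length_mm length in mm (>= 0).
#' @param depth_mm depth of the plane in mm (> 0).
#' @param intr a [depth_intrinsics()] object.
#' @param axis `"rows"` (uses `focal_y`) or `"cols"` (uses `focal_x`).
#' @return integer pixel count, rounded half-up.
#' @seealso [px_to_mm()] for the inverse.
#' @export
mm_to_px <- function(length_mm, depth_mm, intr = depth_intrinsics(),
                     axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  if (any(depth_mm <= 0)) stop("depth_mm must be > 0", call. = FALSE)
  f <- if (axis == "rows") intr$focal_y else intr$focal_x
  as.integer(round_half_up(length_mm * f / depth_mm))
}

#' Convert a pixel count back to a metric length at a given depth
#' @inheritParams mm_to_px
#' @param length_px pixel count (>= 0).
#' @return length in mm.
#' @export
px_to_mm <- function(length_px, depth_mm, intr = depth_intrinsics(),
                     axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  if (any(depth_mm <= 0)) stop("depth_mm must be > 0", call. = FALSE)
  f <- if (axis == "rows") intr$focal_y else intr$focal_x
  length_px * depth_mm / f
}

# ---------------------------------------------------------------------------
# Depth frames and sequences
# ---------------------------------------------------------------------------

#' Construct / validate a depth frame
#'
#' A depth frame is an integer matrix of per-pixel depth readings in mm with
#' row 1 the top of the image; 0 encodes "no reading" (sensor dropout).
#'
#' @param values numeric matrix, coerced to integer mm; all values >= 0.
#' @return integer matrix of class `depth_frame`.
#' @export
depth_frame <- function(values) {
  values <- as.matrix(values)
  if (any(values < 0, na.rm = TRUE)) stop("depth values must be >= 0", call. = FALSE)
  values[is.na(values)] <- 0L
  storage.mode(values) <- "integer"
  class(values) <- c("depth_frame", class(values))
  values
}

#' Construct a frame sequence
#'
#' @param frames list of depth-frame matrices, all of identical shape.
#' @param timestamps optional numeric vector of capture times (s).
#' @return object of class `frame_sequence` (a list with `$frames`).
#' @export
frame_sequence <- function(frames, timestamps = NULL) {
  if (length(frames) == 0L) stop("empty frame sequence", call. = FALSE)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent frame shapes in sequence", call. = FALSE)
  if (!is.null(timestamps) && length(timestamps) != length(frames))
    stop("timestamps length must match frame count", call. = FALSE)
  structure(list(frames = frames, timestamps = timestamps),
            class = "frame_sequence")
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("frame_sequence: %d frame(s) of %d x %d px\n",
              length(x$frames), d[1], d[2]))
  invisible(x)
}

# ---------------------------------------------------------------------------
# File I/O: 16-bit PGM stacks and a headered raw binary dialect
# ---------------------------------------------------------------------------

write_pgm16 <- function(frame, path, ascii = FALSE) {
  frame <- as.matrix(frame)
  storage.mode(frame) <- "integer"
  if (any(frame < 0) || any(frame > 65535L))
    stop("PGM16 values must be in [0, 65535]", call. = FALSE)
  nr <- nrow(frame); nc <- ncol(frame)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(nc, nr), "65535"), con)
    # one image row per line, row-major
    writeLines(apply(frame, 1L, paste, collapse = " "), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n65535\n", nc, nr), con, eos = NULL)
    # PGM stores row-major, 16-bit big-endian
    writeBin(as.integer(t(frame)), con, size = 2L, endian = "big")
  }
  invisible(path)
}

read_pgm16 <- function(path) {
  con <- file(path, "rb")
  closed <- FALSE
  on.exit(if (!closed) close(con))
  read_token <- function() {
    tok <- character(0)
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) break
      if (ch == "#") {  # comment to end of line
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (length(tok) > 0L) break else next
      }
      tok <- c(tok, ch)
    }
    paste(tok, collapse = "")
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path, call. = FALSE)
  if (magic == "P2") {
    close(con); closed <- TRUE
    toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
    vals <- as.integer(toks[-1L])  # drop magic
    nc <- vals[1]; nr <- vals[2]; maxval <- vals[3]
    vals <- vals[-(1:3)]
    if (anyNA(c(nc, nr, maxval)) || length(vals) != nr * nc)
      stop("malformed P2 PGM: ", path, call. = FALSE)
    return(depth_frame(matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)))
  }
  nc <- as.integer(read_token())
  nr <- as.integer(read_token())
  maxval <- as.integer(read_token())
  if (is.na(nc) || is.na(nr) || is.na(maxval))
    stop("malformed PGM header: ", path, call. = FALSE)
  n <- nr * nc
  size <- if (maxval > 255L) 2L else 1L
  vals <- readBin(con, "integer", n = n, size = size,
                  signed = FALSE, endian = "big")
  if (length(vals) != n) stop("truncated PGM data: ", path, call. = FALSE)
  depth_frame(matrix(vals, nrow = nr, ncol = nc, byrow = TRUE))
}

RAW_MAGIC <- "DSQ1"

write_raw_sequence <- function(seq, path) {
  frames <- if (inherits(seq, "frame_sequence")) seq$frames else seq
  d <- dim(frames[[1]])
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(RAW_MAGIC, con, eos = NULL)
  writeBin(as.integer(c(d[2], d[1], length(frames))), con,
           size = 4L, endian = "little")
  for (f in frames)
    writeBin(as.integer(t(f)), con, size = 2L, endian = "little")
  invisible(path)
}

read_raw_sequence <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, nchars = 4L, useBytes = TRUE)
  if (!identical(magic, RAW_MAGIC))
    stop("bad magic in raw depth file: ", path, call. = FALSE)
  hdr <- readBin(con, "integer", n = 3L, size = 4L, endian = "little")
  nc <- hdr[1]; nr <- hdr[2]; k <- hdr[3]
  frames <- vector("list", k)
  for (i in seq_len(k)) {
    vals <- readBin(con, "integer", n = nr * nc, size = 2L,
                    signed = FALSE, endian = "little")
    if (length(vals) != nr * nc) stop("truncated raw depth file", call. = FALSE)
    frames[[i]] <- depth_frame(matrix(vals, nrow = nr, ncol = nc, byrow = TRUE))
  }
  frame_sequence(frames)
}

#' Read a depth-frame sequence from disk
#'
#' Supported dialects: `pgm16-stack` (a directory of 16-bit PGM files, one
#' per frame, ordered by their zero-padded numeric suffix) and `raw` (a single
#' headered little-endian binary file).  Values are depth in mm; unreadable
#' pixels are 0.
#'
#' @param path directory (`pgm16-stack`) or file (`raw`).
#' @param dialect one of `"pgm16-stack"`, `"raw"`.
#' @return a [frame_sequence()].
#' @export
read_depth_sequence <- function(path, dialect = c("pgm16-stack", "raw")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such path: ", path, call. = FALSE)
  if (dialect == "raw") return(read_raw_sequence(path))
  files <- sort(list.files(path, pattern = "\\.pgm$", full.names = TRUE))
  if (length(files) == 0L) stop("no .pgm files under ", path, call. = FALSE)
  frame_sequence(lapply(files, read_pgm16))
}

#' Write a depth-frame sequence to disk
#'
#' @param seq a [frame_sequence()] or list of frames.
#' @param path output directory (`pgm16-stack`) or file (`raw`).
#' @param dialect one of `"pgm16-stack"`, `"raw"`.
#' @param prefix file-name prefix for the PGM stack.
#' @param ascii write ASCII (P2) instead of binary (P5) PGM.
#' @return `path`, invisibly.
#' @export
write_depth_sequence <- function(seq, path,
                                 dialect = c("pgm16-stack", "raw"),
                                 prefix = "frame", ascii = FALSE) {
  dialect <- match.arg(dialect)
  frames <- if (inherits(seq, "frame_sequence")) seq$frames else seq
  if (dialect == "raw") return(write_raw_sequence(frames, path))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(frames))
    write_pgm16(frames[[i]],
                file.path(path, sprintf("%s_%05d.pgm", prefix, i)),
                ascii = ascii)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Key-value config files
# ---------------------------------------------------------------------------

#' Read a key-value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment.  Values that parse
#' as numbers are returned numeric.
#'
#' @param path file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) < 2L) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(parts[1])
    val <- trimws(paste(parts[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Write a key-value configuration file
#' @param x named list of scalars.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(x, path) {
  stopifnot(is.list(x), !is.null(names(x)))
  fmt <- vapply(x, function(v) {
    if (is.numeric(v)) format(v, digits = 15) else as.character(v)
  }, character(1))
  writeLines(paste(names(x), "=", fmt), path)
  invisible(path)
}
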