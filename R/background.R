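# Background construction and silhouette segmentation.

#' Build the reference background frame
#'
#' Per-pixel temporal mean of the empty-scene sequence, using only valid
#' (nonzero) readings, rounded to integer mm.  A pixel with no valid reading
#' in any frame stays 0.  Frame order does not matter.
#'
#' @param seq a [frame_sequence()] or list of depth-frame matrices.
#' @return a [depth_frame()] of the same shape.
#' @export
build_background <- function(seq) {
  frames <- if (inherits(seq, "frame_sequence")) seq$frames else seq
  if (length(frames) == 0L) stop("empty frame sequence", call. = FALSE)
  d <- dim(frames[[1]])
  acc <- matrix(0, d[1], d[2])
  cnt <- matrix(0L, d[1], d[2])
  for (f in frames) {
    if (!identical(dim(f), d)) stop("inconsistent frame shapes", call. = FALSE)
    valid <- f > 0L
    acc <- acc + ifelse(valid, f, 0)
    cnt <- cnt + valid
  }
  out <- matrix(0L, d[1], d[2])
  has <- cnt > 0L
  out[has] <- as.integer(round_half_up(acc[has] / cnt[has]))
  depth_frame(out)
}

#' Foreground mask by background subtraction
#'
#' A pixel is foreground when its depth differs from the background by at
#' least the threshold: `|DF - BF| < th` gives 0, otherwise 1 (strict
#' inequality, so a difference of exactly `th` is foreground).  Pixels with
#' no reading in `df` (value 0) are never foreground, so sensor dropout is
#' not mistaken for the subject.
#'
#' @param df current depth frame.
#' @param bf background frame (same shape).
#' @param th depth threshold in mm (default 150, chosen to separate the
#'   subject's feet from the floor).
#' @return binary integer matrix (0/1) of class `foreground_mask`.
#' @export
foreground_mask <- function(df, bf, th = 150) {
  if (!identical(dim(df), dim(bf)))
    stop("frame/background shape mismatch", call. = FALSE)
  if (th <= 0) stop("th must be > 0", call. = FALSE)
  m <- (abs(df - bf) >= th) & (df > 0L)
  m <- matrix(as.integer(m), nrow(df), ncol(df))
  class(m) <- c("foreground_mask", class(m))
  m
}

#' Extract the largest connected foreground component
#'
#' Labels connected components (8-connectivity by default: diagonal limb
#' pixels must not sever the silhouette) and keeps the one with the most
#' pixels, assumed to be the subject.  Size ties go to the component whose
#' first pixel comes earliest in row-major scan order.
#'
#' @param mask binary matrix (a `foreground_mask` or any 0/1 matrix).
#' @param connectivity 4 or 8.
#' @return object of class `silhouette`: list with `bits` (binary matrix of
#'   the single component) and its tight bounding box `first_row`,
#'   `last_row`, `first_col`, `last_col` (1-based).
#' @export
largest_silhouette <- function(mask, connectivity = 8L) {
  mask <- matrix(as.integer(mask != 0L), nrow(mask), ncol(mask))
  if (!any(mask == 1L)) stop("no subject: empty foreground mask", call. = FALSE)
  labels <- .label_components_cpp(mask, as.integer(connectivity))
  sizes <- tabulate(labels[labels > 0L])
  # which.max takes the first maximum; labels are assigned in row-major scan
  # order, so this realises the documented tie-break
  best <- which.max(sizes)
  bits <- matrix(as.integer(labels == best), nrow(mask), ncol(mask))
  silhouette(bits)
}

#' Construct a silhouette object from a binary matrix
#' @param bits binary matrix containing the component.
#' @return a `silhouette` (see [largest_silhouette()]).
#' @export
silhouette <- function(bits) {
  bits <- matrix(as.integer(bits != 0L), nrow(bits), ncol(bits))
  idx <- which(bits == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty silhouette", call. = FALSE)
  structure(list(bits = bits,
                 first_row = min(idx[, 1]), last_row = max(idx[, 1]),
                 first_col = min(idx[, 2]), last_col = max(idx[, 2])),
            class = "silhouette")
}

#' @export
print.silhouette <- function(x, ...) {
  cat(sprintf("silhouette: %d px, rows %d-%d, cols %d-%d\n",
              sum(x$bits), x$first_row, x$last_row, x$first_col, x$last_col))
  invisible(x)
}

# columns of the silhouette on a given row (integer vector, possibly empty)
sil_cols <- function(sil, row) {
  if (row < 1L || row > nrow(sil$bits)) return(integer(0))
  which(sil$bits[row, ] == 1L)
}

#' Export a binary mask as an 8-bit PGM image for inspection
#' @param mask binary matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mask_pgm <- function(mask, path) {
  m <- matrix(as.integer(mask != 0L) * 255L, nrow(mask), ncol(mask))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n255\n", ncol(m), nrow(m)), con, eos = NULL)
  writeBin(as.integer(t(m)), con, size = 1L)
  invisible(path)
}
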