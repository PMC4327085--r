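# Side-view joint localization: per-frame estimation of head, shoulder,
# elbow, hip, knee and ankle during the Get Up and Go Test, using the
# calibrated body model.  Frames are processed independently: no temporal
# smoothing.

JOINTS <- c("head", "shoulder", "elbow", "hip", "knee", "ankle")

#' Rasterize an integer line segment
#'
#' Rounded-DDA integer line: 8-connected, endpoint-inclusive, deterministic.
#' Used to draw the rotating vectors whose overlap with a limb mask is
#' maximized.
#'
#' @param r0,c0 start pixel (1-based row/col).
#' @param r1,c1 end pixel.
#' @return 2-column integer matrix of (row, col) raster pixels.
#' @export
raster_segment <- function(r0, c0, r1, c1) {
  r0 <- round_half_up(r0); c0 <- round_half_up(c0)
  r1 <- round_half_up(r1); c1 <- round_half_up(c1)
  n <- max(abs(r1 - r0), abs(c1 - c0))
  if (n == 0) return(cbind(row = as.integer(r0), col = as.integer(c0)))
  t <- 0:n
  cbind(row = as.integer(round_half_up(r0 + t * (r1 - r0) / n)),
        col = as.integer(round_half_up(c0 + t * (c1 - c0) / n)))
}

# count raster pixels of the segment that fall inside a binary mask
segment_overlap <- function(bits, r0, c0, r1, c1) {
  px <- raster_segment(r0, c0, r1, c1)
  keep <- px[, 1] >= 1L & px[, 1] <= nrow(bits) &
          px[, 2] >= 1L & px[, 2] <= ncol(bits)
  if (!any(keep)) return(0L)
  px <- px[keep, , drop = FALSE]
  sum(bits[cbind(px[, 1], px[, 2])])
}

# Sweep a fixed-length vector anchored at `anchor` over `angles` (degrees);
# `dir_fun(a)` gives the unit direction (drow, dcol).  Returns the endpoint
# of the first angle with maximal mask overlap (ties -> smallest angle).
rotating_fit <- function(bits, anchor, len, angles, dir_fun) {
  best <- -1L; best_end <- NULL; best_angle <- NA_real_
  for (a in angles) {
    d <- dir_fun(a)
    er <- anchor[["row"]] + len * d[1]
    ec <- anchor[["col"]] + len * d[2]
    ov <- segment_overlap(bits, anchor[["row"]], anchor[["col"]], er, ec)
    if (ov > best) {
      best <- ov
      best_end <- px_coord(round_half_up(er), round_half_up(ec))
      best_angle <- a
    }
  }
  list(endpoint = best_end, angle = best_angle, overlap = best)
}

# re-project `provisional` to lie exactly `len` px from `anchor` along the
# anchor -> provisional direction (the paper's segment-length constraint for
# shoulder and knee); a degenerate zero direction falls back to `fallback`.
reproject_to_length <- function(anchor, provisional, len,
                                fallback = c(1, 0)) {
  d <- c(provisional[["row"]] - anchor[["row"]],
         provisional[["col"]] - anchor[["col"]])
  nrm <- sqrt(sum(d^2))
  u <- if (nrm == 0) fallback / sqrt(sum(fallback^2)) else d / nrm
  px_coord(round_half_up(anchor[["row"]] + len * u[1]),
           round_half_up(anchor[["col"]] + len * u[2]))
}

#' Locate the head joint in a side-view frame
#'
#' Reuses the calibrated head shift: the head row is `shift_row` rows below
#' the first silhouette row; the column is the mean of the silhouette column
#' indices on that row.
#'
#' @param sil frame [silhouette()].
#' @param model calibrated `body_model`.
#' @return named row/col vector.
#' @export
locate_head_side <- function(sil, model) {
  row <- sil$first_row + model$shift_row
  cols <- sil_cols(sil, row)
  if (length(cols) == 0L) stop("tracking error: empty head row", call. = FALSE)
  px_coord(row, round_half_up(mean(cols)))
}

#' Locate the shoulder joint in a side-view frame
#'
#' Provisional shoulder: `hs_dist` rows below the head, column midway between
#' the first and last silhouette columns on that row.  The estimate is then
#' re-projected along the head-to-provisional direction so the head-shoulder
#' segment length equals `hs_dist` exactly -- this keeps the joint near its
#' true position while the trunk leans during stand-up.
#'
#' @param sil frame [silhouette()].
#' @param head head coordinate from [locate_head_side()].
#' @param model calibrated `body_model`.
#' @return named row/col vector.
#' @export
locate_shoulder_side <- function(sil, head, model) {
  prow <- head[["row"]] + model$hs_dist
  cols <- sil_cols(sil, prow)
  if (length(cols) == 0L)
    stop("tracking error: empty shoulder row", call. = FALSE)
  prov <- px_coord(prow, round_half_up((min(cols) + max(cols)) / 2))
  reproject_to_length(head, prov, model$hs_dist)
}

#' Select the near-side (sensor-facing) region of the silhouette
#'
#' Half an ankle-knee distance above the lowest silhouette row, the column
#' with the smallest depth marks the near leg.  A square window of side
#' `ak_dist` centred there is cleaned of pixels deviating more than `gap` mm
#' from the central pixel; the mean depth of the survivors is the reference,
#' and the region is every silhouette pixel within `gap` mm of it.  This
#' isolates the limbs closest to the sensor, excluding the far leg/arm.
#'
#' @param df depth frame.
#' @param sil frame [silhouette()].
#' @param model calibrated `body_model`.
#' @param gap depth gap in mm (default 80).
#' @return object of class `near_side_region`: list with binary `bits` and
#'   `reference_depth` (mm).
#' @export
near_side_region <- function(df, sil, model, gap = 80) {
  r <- sil$last_row - model$ak_dist %/% 2L
  r <- max(min(r, sil$last_row), sil$first_row)
  cols <- sil_cols(sil, r)
  cols <- cols[df[r, cols] > 0L]
  if (length(cols) == 0L)
    stop("tracking error: no valid depths on near-side seed row", call. = FALSE)
  cc <- cols[which.min(df[r, cols])]
  half <- model$ak_dist %/% 2L
  rows_w <- max(1L, r - half):min(nrow(df), r + half)
  cols_w <- max(1L, cc - half):min(ncol(df), cc + half)
  w <- df[rows_w, cols_w]
  valid <- w > 0L & sil$bits[rows_w, cols_w] == 1L
  centre <- df[r, cc]
  keep <- valid & abs(w - as.numeric(centre)) <= gap
  # if the central pixel is itself an outlier (a lone noise spike), almost
  # every window pixel is discarded; re-centre on the window median instead
  if (sum(keep) < 0.25 * sum(valid)) {
    centre <- median(w[valid])
    keep <- valid & abs(w - as.numeric(centre)) <= gap
  }
  if (!any(keep))
    stop("tracking error: near-side window entirely discarded", call. = FALSE)
  ref <- mean(w[keep])
  bits <- matrix(0L, nrow(df), ncol(df))
  inside <- sil$bits == 1L & df > 0L & abs(df - ref) <= gap
  bits[inside] <- 1L
  structure(list(bits = bits, reference_depth = ref),
            class = "near_side_region")
}

region_cols <- function(region, row) {
  if (row < 1L || row > nrow(region$bits)) return(integer(0))
  which(region$bits[row, ] == 1L)
}

#' Locate the ankle joint in a side-view frame
#'
#' Mirror of the head rule from the bottom: 40 mm above the last silhouette
#' row, column the mean of the near-side region columns there (the near-side
#' restriction keeps the far leg out when the legs separate during gait).
#'
#' @param sil frame [silhouette()].
#' @param region [near_side_region()] of the frame.
#' @param depth_mm frame subject depth (mm) for the 40-mm conversion.
#' @param intr a [depth_intrinsics()].
#' @param model calibrated `body_model`.
#' @param shift_mm bottom offset (default 40 mm).
#' @return named row/col vector.
#' @export
locate_ankle_side <- function(sil, region, depth_mm,
                              intr = depth_intrinsics(), model = NULL,
                              shift_mm = 40) {
  row <- sil$last_row - mm_to_px(shift_mm, depth_mm, intr, "rows")
  cols <- region_cols(region, row)
  if (length(cols) == 0L)
    stop("tracking error: empty ankle row in near-side region", call. = FALSE)
  px_coord(row, round_half_up(mean(cols)))
}

#' Locate the knee joint in a side-view frame
#'
#' Provisional knee `ak_dist` rows above the ankle (near-side column mean),
#' then re-projected so the ankle-knee segment equals `ak_dist` exactly,
#' following the shank direction when it is flexed.
#'
#' @param region [near_side_region()] of the frame.
#' @param ankle ankle coordinate.
#' @param model calibrated `body_model`.
#' @return named row/col vector.
#' @export
locate_knee_side <- function(region, ankle, model) {
  prow <- ankle[["row"]] - model$ak_dist
  cols <- region_cols(region, prow)
  if (length(cols) == 0L)
    stop("tracking error: empty knee row in near-side region", call. = FALSE)
  prov <- px_coord(prow, round_half_up(mean(cols)))
  reproject_to_length(ankle, prov, model$ak_dist, fallback = c(-1, 0))
}

#' Locate the elbow joint by a rotating vector
#'
#' Extracts an arm sub-region with the same windowed depth-gap rule used for
#' the near side, in a window of side `se_dist` centred `se_dist / 2` rows
#' below the shoulder at the shoulder column.  A vector of length `se_dist`
#' anchored at the shoulder is swept over the lower half-plane
#' (theta = 2, 4, ..., 178 degrees from the horizontal image axis; 90 degrees
#' is straight down); the elbow is the endpoint of the sweep angle with the
#' most raster pixels inside the arm sub-region (ties: smallest angle).
#'
#' @param df depth frame.
#' @param sil frame [silhouette()].
#' @param shoulder shoulder coordinate.
#' @param model calibrated `body_model`.
#' @param gap depth gap in mm (default 80).
#' @param min_pixels smallest usable arm sub-region (default 10 px); below
#'   it the joint is reported missing rather than fitted.
#' @param step_deg sweep step (default 2 degrees).
#' @return named row/col vector.
#' @export
locate_elbow_side <- function(df, sil, shoulder, model, gap = 80,
                              min_pixels = 10L, step_deg = 2) {
  se <- model$se_dist
  cr <- as.integer(round_half_up(shoulder[["row"]] + se %/% 2L))
  cc <- as.integer(round_half_up(shoulder[["col"]]))
  if (cr < 1L || cr > nrow(df) || cc < 1L || cc > ncol(df))
    stop("tracking error: elbow window centre outside frame", call. = FALSE)
  half <- se %/% 2L
  rows_w <- max(1L, cr - half):min(nrow(df), cr + half)
  cols_w <- max(1L, cc - half):min(ncol(df), cc + half)
  centre <- df[cr, cc]
  if (centre <= 0L)
    stop("tracking error: no depth at elbow window centre", call. = FALSE)
  w <- df[rows_w, cols_w]
  keep <- w > 0L & abs(w - as.numeric(centre)) <= gap
  if (!any(keep))
    stop("tracking error: elbow window entirely discarded", call. = FALSE)
  ref <- mean(w[keep])
  bits <- matrix(0L, nrow(df), ncol(df))
  sub <- sil$bits[rows_w, cols_w] == 1L & w > 0L & abs(w - ref) <= gap
  bits[rows_w, cols_w][sub] <- 1L
  if (sum(bits) < min_pixels)
    stop("tracking error: arm sub-region too small", call. = FALSE)
  fit <- rotating_fit(bits, shoulder, se,
                      angles = seq(step_deg, 180 - step_deg, by = step_deg),
                      dir_fun = function(a) {
                        th <- a * pi / 180
                        c(sin(th), cos(th))
                      })
  if (fit$overlap <= 0L)
    stop("tracking error: no sweep angle overlaps the arm", call. = FALSE)
  fit$endpoint
}

#' Locate the hip joint by a rotating vector
#'
#' A vector of length `kh_dist` anchored at the knee is swept over the upper
#' half-plane (gamma = 4, 6, ..., 176 degrees from the horizontal image axis;
#' 90 degrees is straight up); the hip is the endpoint of the angle whose
#' raster overlaps the near-side thigh/torso region most (ties: smallest
#' angle).  Seated frames, with the thigh near horizontal, select a
#' near-horizontal angle; upright frames a near-vertical one.
#'
#' @param region [near_side_region()] of the frame.
#' @param knee knee coordinate.
#' @param model calibrated `body_model`.
#' @param start_deg first sweep angle (default 4 degrees).
#' @param step_deg sweep step (default 2 degrees).
#' @return named row/col vector.
#' @export
locate_hip_side <- function(region, knee, model, start_deg = 4, step_deg = 2) {
  fit <- rotating_fit(region$bits, knee, model$kh_dist,
                      angles = seq(start_deg, 180 - start_deg, by = step_deg),
                      dir_fun = function(a) {
                        g <- a * pi / 180
                        c(-sin(g), cos(g))
                      })
  if (fit$overlap <= 0L)
    stop("tracking error: no sweep angle overlaps the thigh", call. = FALSE)
  fit$endpoint
}

# ---------------------------------------------------------------------------
# Trajectories
# ---------------------------------------------------------------------------

#' Construct a joint trajectory container
#'
#' @param coords numeric array `K x 6 x 2` (frames x joints x row/col), `NA`
#'   marking a missing joint in a frame.  Joint order: head, shoulder, elbow,
#'   hip, knee, ankle.
#' @return object of class `joint_trajectory`.
#' @export
joint_trajectory <- function(coords) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 6L,
            dim(coords)[3] == 2L)
  dimnames(coords) <- list(NULL, JOINTS, c("row", "col"))
  structure(list(coords = coords, joints = JOINTS),
            class = "joint_trajectory")
}

#' @export
print.joint_trajectory <- function(x, ...) {
  k <- dim(x$coords)[1]
  miss <- apply(x$coords[, , 1, drop = FALSE], 2, function(v) sum(is.na(v)))
  cat(sprintf("joint_trajectory: %d frame(s)\n", k))
  cat("  missing per joint:",
      paste(sprintf("%s=%d", x$joints, miss), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.joint_trajectory <- function(x, ...) {
  k <- dim(x$coords)[1]
  do.call(rbind, lapply(seq_along(x$joints), function(j) {
    data.frame(frame = seq_len(k), joint = x$joints[j],
               row = x$coords[, j, "row"], col = x$coords[, j, "col"])
  }))
}

#' Track the six joints over a depth-frame sequence
#'
#' For every frame: background subtraction, largest-component silhouette,
#' then the six side-view locators, each frame independently.  A locator
#' failure (empty row, degenerate region, no subject) marks that joint -- or
#' the whole frame -- missing rather than aborting the run.
#'
#' @param seq a [frame_sequence()] of the test execution.
#' @param bf background frame.
#' @param model calibrated `body_model` from [calibrate()].
#' @param intr a [depth_intrinsics()].
#' @param th foreground threshold (mm, default 150).
#' @param gap near-side depth gap (mm, default 80).
#' @param verbose print per-frame timing.
#' @return a [joint_trajectory()] with one entry per frame.
#' @export
track_sequence <- function(seq, bf, model, intr = depth_intrinsics(),
                           th = 150, gap = 80, verbose = FALSE) {
  frames <- if (inherits(seq, "frame_sequence")) seq$frames else seq
  k <- length(frames)
  coords <- array(NA_real_, dim = c(k, 6L, 2L))
  for (i in seq_len(k)) {
    t0 <- proc.time()[["elapsed"]]
    df <- frames[[i]]
    res <- track_frame(df, bf, model, intr, th, gap)
    for (j in seq_along(JOINTS)) {
      jc <- res[[JOINTS[j]]]
      if (!is.null(jc)) coords[i, j, ] <- jc
    }
    if (verbose)
      message(sprintf("frame %d: %.3f s", i, proc.time()[["elapsed"]] - t0))
  }
  joint_trajectory(coords)
}

# single-frame tracking; returns a named list of coordinates, NULL = missing
track_frame <- function(df, bf, model, intr, th = 150, gap = 80) {
  out <- setNames(vector("list", 6L), JOINTS)
  sil <- tryCatch(largest_silhouette(foreground_mask(df, bf, th)),
                  error = function(e) NULL)
  if (is.null(sil)) return(out)
  zf <- tryCatch(subject_depth(df, sil), error = function(e) NULL)
  if (is.null(zf)) return(out)

  out$head <- tryCatch(locate_head_side(sil, model), error = function(e) NULL)
  if (!is.null(out$head)) {
    out$shoulder <- tryCatch(locate_shoulder_side(sil, out$head, model),
                             error = function(e) NULL)
    if (!is.null(out$shoulder))
      out$elbow <- tryCatch(locate_elbow_side(df, sil, out$shoulder, model,
                                              gap = gap),
                            error = function(e) NULL)
  }
  region <- tryCatch(near_side_region(df, sil, model, gap = gap),
                     error = function(e) NULL)
  if (!is.null(region)) {
    out$ankle <- tryCatch(locate_ankle_side(sil, region, zf, intr, model),
                          error = function(e) NULL)
    if (!is.null(out$ankle)) {
      out$knee <- tryCatch(locate_knee_side(region, out$ankle, model),
                           error = function(e) NULL)
      if (!is.null(out$knee))
        out$hip <- tryCatch(locate_hip_side(region, out$knee, model),
                            error = function(e) NULL)
    }
  }
  out
}

#' Write / read a trajectory CSV
#'
#' Long format with header `frame,joint,row,col,missing`; missing joints are
#' written as `row = 0, col = 0, missing = 1` (the null-sentinel convention
#' of marker logs), and read back as `NA` coordinates.
#'
#' @param traj a [joint_trajectory()].
#' @param path file path.
#' @return `path` invisibly / a `joint_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  d <- as.data.frame(traj)
  miss <- is.na(d$row) | is.na(d$col)
  d$missing <- as.integer(miss)
  d$row[miss] <- 0
  d$col[miss] <- 0
  write.csv(d[order(d$frame, match(d$joint, JOINTS)), ], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "joint", "row", "col", "missing")
  if (!all(need %in% names(d)))
    stop("trajectory CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  k <- max(d$frame)
  coords <- array(NA_real_, dim = c(k, 6L, 2L))
  for (j in seq_along(JOINTS)) {
    dj <- d[d$joint == JOINTS[j] & d$missing == 0L, ]
    coords[dj$frame, j, 1] <- dj$row
    coords[dj$frame, j, 2] <- dj$col
  }
  joint_trajectory(coords)
}

#' Linearly interpolate missing frames of a trajectory
#'
#' Post-hoc utility producing the continuous curves used for plotting; the
#' core tracker never interpolates.  Leading/trailing gaps are left missing.
#'
#' @param traj a [joint_trajectory()].
#' @return a [joint_trajectory()] with interior gaps filled.
#' @export
interpolate_trajectory <- function(traj) {
  coords <- traj$coords
  k <- dim(coords)[1]
  if (k < 2L) return(traj)
  for (j in seq_len(dim(coords)[2])) {
    for (ax in 1:2) {
      v <- coords[, j, ax]
      ok <- which(!is.na(v))
      if (length(ok) >= 2L) {
        gaps <- setdiff(seq.int(min(ok), max(ok)), ok)
        if (length(gaps) > 0L)
          v[gaps] <- stats::approx(ok, v[ok], xout = gaps)$y
        coords[, j, ax] <- v
      }
    }
  }
  joint_trajectory(coords)
}
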