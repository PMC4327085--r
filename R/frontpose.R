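# Front-plane pose analysis: anthropometric joint localization on the single
# calibration frame, and derivation of the per-subject body model used during
# side-view tracking.

#' Anthropometric survey datasets used to derive the hip coefficient
#'
#' Printed per-dataset anthropometric measurements (stature, head height,
#' buttock height, all cm) from which the stature/head ratio `R` and the hip
#' coefficient `c` are derived.  Dataset ids follow the survey's numbering
#' (e.g. 7 = "AIR FORCE WOMEN-1968", 51 = "ITALIAN MILITARY-1961").
#'
#' Known print inconsistencies, kept as printed: dataset 8's stature minus
#' buttock height cell (80.61 vs the recomputed 80.69) and dataset 51's ratio
#' (7.64 where division rounds to 7.65).
#'
#' @return data.frame with columns `dataset`, `stature`, `head_height`,
#'   `ratio`, `buttock_height`, `s_minus_bh`, `c`.
#' @export
anthropometric_table <- function() {
  data.frame(
    dataset        = c(10L, 8L, 7L, 9L, 51L, 21L, 20L),
    stature        = c(161.3, 162.77, 162.1, 161.92, 170.62, 174.72, 177.1),
    head_height    = c(22.56, 22.08, 21.91, 21.76, 22.31, 22.45, 22.4),
    ratio          = c(7.15, 7.37, 7.4, 7.44, 7.64, 7.78, 7.9),
    buttock_height = c(84.14, 82.08, 82.21, 82.09, 86.56, 89.95, 91.16),
    s_minus_bh     = c(77.16, 80.61, 79.89, 79.83, 84.06, 84.77, 85.94),
    c              = c(3.42, 3.65, 3.65, 3.67, 3.77, 3.78, 3.84)
  )
}

round2 <- function(x) floor(x * 100 + 0.5) / 100  # 2 decimals, half-up

#' Stature-to-head-height ratio from survey measurements
#'
#' @param stature stature in cm (> 0).
#' @param head_height head height in cm (> 0).
#' @return `stature / head_height`, reported to 2 decimals (half-up).
#' @export
table1_ratio <- function(stature, head_height) {
  if (any(stature <= 0)) stop("stature must be > 0", call. = FALSE)
  if (any(head_height <= 0)) stop("head_height must be > 0", call. = FALSE)
  round2(stature / head_height)
}

#' Empirical hip coefficient from survey measurements
#'
#' The distance from the top of the head to the hip (stature minus buttock
#' height) expressed in head heights.
#'
#' @param stature stature in cm.
#' @param buttock_height hip-joint height from the floor in cm
#'   (0 < buttock_height < stature).
#' @param head_height head height in cm (> 0).
#' @return `(stature - buttock_height) / head_height` to 2 decimals.
#' @export
table1_coefficient <- function(stature, buttock_height, head_height) {
  if (any(head_height <= 0)) stop("head_height must be > 0", call. = FALSE)
  if (any(!(stature > buttock_height & buttock_height > 0)))
    stop("need stature > buttock_height > 0", call. = FALSE)
  round2((stature - buttock_height) / head_height)
}

#' Hip coefficient from the stature/head ratio
#'
#' Piecewise-constant lookup calibrated on the survey datasets: the number of
#' head heights between head top and hip as a function of the ratio `R`
#' between total height and head height.  Breakpoints are left-closed on the
#' upper branch (R = 6.4 maps to 3.4, R = 8.8 to 4.2).
#'
#' @param R stature/head-height ratio (> 0), pixel- or cm-derived.
#' @return coefficient in \{3.2, 3.4, 3.6, 3.8, 4, 4.2\}.
#' @export
coefficient_c <- function(R) {
  if (any(R <= 0)) stop("R must be > 0", call. = FALSE)
  values <- c(3.2, 3.4, 3.6, 3.8, 4, 4.2)
  values[findInterval(R, c(6.4, 7.2, 7.5, 8, 8.8)) + 1L]
}

# pixel coordinate helper: named numeric c(row, col), 1-based
px_coord <- function(row, col) c(row = as.numeric(row), col = as.numeric(col))

#' Silhouette height in pixels
#'
#' @param sil a [silhouette()].
#' @return `last_row - first_row` (px).
#' @export
human_height <- function(sil) sil$last_row - sil$first_row

# median depth of the subject's silhouette pixels (mm); the single plane
# depth at which body-scale mm quantities are converted to pixels
subject_depth <- function(df, sil) {
  z <- df[sil$bits == 1L]
  z <- z[z > 0L]
  if (length(z) == 0L) stop("silhouette has no valid depth readings", call. = FALSE)
  median(z)
}

#' Find the shoulder-top row by the width-difference scan
#'
#' Scans the silhouette from 100 mm below its top row downward in 40-mm row
#' steps, counting silhouette columns per sampled row, until the scanned span
#' reaches one third of the silhouette height.  The sampled row with the
#' largest width increase over the previous sampled row marks the top of the
#' shoulders.  Ties (including the all-flat case) go to the topmost sampled
#' row.
#'
#' @param sil a [silhouette()].
#' @param depth_mm subject plane depth (mm) used for mm-to-px conversion.
#' @param intr a [depth_intrinsics()].
#' @param step_mm scan step (default 40 mm, sized to catch the neck-to-
#'   shoulder widening).
#' @param start_offset_mm offset below the head top where the scan starts
#'   (default 100 mm).
#' @return sampled row index (1-based).
#' @export
find_row_max_dim <- function(sil, depth_mm, intr = depth_intrinsics(),
                             step_mm = 40, start_offset_mm = 100) {
  start <- sil$first_row + mm_to_px(start_offset_mm, depth_mm, intr, "rows")
  step <- max(1L, mm_to_px(step_mm, depth_mm, intr, "rows"))
  last <- start + human_height(sil) %/% 3L
  last <- min(last, sil$last_row)
  if (last < start + step)
    stop("calibration error: silhouette too short for shoulder scan",
         call. = FALSE)
  rows <- seq.int(start, last, by = step)
  widths <- vapply(rows, function(r) length(sil_cols(sil, r)), integer(1))
  diffs <- c(0L, diff(widths))  # first sampled row carries a zero difference
  rows[which.max(diffs)]
}

#' Locate the head joint on the front-pose silhouette
#'
#' The head row sits one third of the way from the silhouette top to the
#' shoulder-top row; that offset (`shift_row`) is retained in the body model
#' and reused in every side-view frame.  The head column is the midpoint of
#' the first and last silhouette columns on the head row.
#'
#' @param sil a [silhouette()].
#' @param row_max_dim shoulder-top row from [find_row_max_dim()].
#' @return list with `joint` (named row/col vector) and `shift_row` (px).
#' @export
locate_head_front <- function(sil, row_max_dim) {
  if (row_max_dim <= sil$first_row)
    stop("calibration error: shoulder row above head top", call. = FALSE)
  shift_row <- (row_max_dim - sil$first_row) %/% 3L
  head_row <- sil$first_row + shift_row
  cols <- sil_cols(sil, head_row)
  if (length(cols) == 0L)
    stop("calibration error: empty head row", call. = FALSE)
  col <- round_half_up((min(cols) + max(cols)) / 2)
  list(joint = px_coord(head_row, col), shift_row = shift_row)
}

#' Head height in pixels
#'
#' Distance from the silhouette top to the shoulder-top row minus a fixed
#' 100-mm neck allowance.
#'
#' @inheritParams locate_head_front
#' @param depth_mm subject plane depth (mm).
#' @param intr a [depth_intrinsics()].
#' @param neck_mm neck-height allowance (default 100 mm).
#' @return head height (px, > 0).
#' @export
head_height_px <- function(sil, row_max_dim, depth_mm,
                           intr = depth_intrinsics(), neck_mm = 100) {
  hh <- (row_max_dim - sil$first_row) - mm_to_px(neck_mm, depth_mm, intr, "rows")
  if (hh <= 0)
    stop("calibration error: non-positive head height", call. = FALSE)
  hh
}

#' Locate the shoulder joint on the front-pose silhouette
#'
#' 40 mm below the shoulder-top row; the column is 40 mm inboard of the first
#' silhouette column on that row (arm side configurable for mirrored setups).
#'
#' @inheritParams head_height_px
#' @param shift_mm vertical and horizontal shift (default 40 mm).
#' @param arm_side `"left"` (frame-left) or `"right"`.
#' @return named row/col vector.
#' @export
locate_shoulder_front <- function(sil, row_max_dim, depth_mm,
                                  intr = depth_intrinsics(), shift_mm = 40,
                                  arm_side = c("left", "right")) {
  arm_side <- match.arg(arm_side)
  row <- row_max_dim + mm_to_px(shift_mm, depth_mm, intr, "rows")
  cols <- sil_cols(sil, row)
  if (length(cols) == 0L)
    stop("calibration error: empty shoulder row", call. = FALSE)
  dx <- mm_to_px(shift_mm, depth_mm, intr, "cols")
  col <- if (arm_side == "left") min(cols) + dx else max(cols) - dx
  if (col < 1L || col > ncol(sil$bits) || sil$bits[row, col] != 1L)
    stop("calibration error: shoulder shift lands outside silhouette",
         call. = FALSE)
  px_coord(row, col)
}

#' Hip row from head height and the hip coefficient
#'
#' @param sil a [silhouette()].
#' @param head_height head height (px).
#' @param c hip coefficient from [coefficient_c()].
#' @return row index `first_row + round(c * head_height)`.
#' @export
locate_hip_row <- function(sil, head_height, c) {
  row <- sil$first_row + round_half_up(c * head_height)
  if (row > sil$last_row)
    stop("calibration error: hip row below silhouette", call. = FALSE)
  as.integer(row)
}

#' Locate ankle and knee on the front-pose silhouette
#'
#' The ankle row is 40 mm above the silhouette bottom (inside the foot); the
#' ankle-knee pixel distance is 0.2 times the silhouette height, which places
#' the knee row.  Columns are silhouette column means on each row.
#'
#' @param sil a [silhouette()].
#' @param depth_mm subject plane depth (mm).
#' @param intr a [depth_intrinsics()].
#' @param shift_mm bottom offset (default 40 mm).
#' @return list with `ankle`, `knee` (row/col vectors) and `ak_dist` (px).
#' @export
locate_ankle_knee_front <- function(sil, depth_mm, intr = depth_intrinsics(),
                                    shift_mm = 40) {
  ankle_row <- sil$last_row - mm_to_px(shift_mm, depth_mm, intr, "rows")
  acols <- sil_cols(sil, ankle_row)
  if (length(acols) == 0L)
    stop("calibration error: empty ankle row", call. = FALSE)
  ak_dist <- as.integer(round_half_up(0.2 * human_height(sil)))
  knee_row <- ankle_row - ak_dist
  kcols <- sil_cols(sil, knee_row)
  if (length(kcols) == 0L)
    stop("calibration error: empty knee row", call. = FALSE)
  list(ankle = px_coord(ankle_row, round_half_up(mean(acols))),
       knee = px_coord(knee_row, round_half_up(mean(kcols))),
       ak_dist = ak_dist)
}

#' Locate wrist and elbow through the arm gap
#'
#' On the hip row, the outstretched arm is separated from the torso by a gap
#' in the silhouette column indices.  The sub-region beyond the gap is the
#' arm; its lowest row is the end of the hand, the wrist sits half a head
#' height above it, and the elbow is the midpoint of wrist and shoulder.
#'
#' @param sil a [silhouette()].
#' @param hip_row row index from [locate_hip_row()].
#' @param head_height head height (px).
#' @param shoulder shoulder coordinate from [locate_shoulder_front()].
#' @param arm_side `"left"` (frame-left) or `"right"`.
#' @return list with `wrist` and `elbow` row/col vectors.
#' @export
locate_arm_chain <- function(sil, hip_row, head_height, shoulder,
                             arm_side = c("left", "right")) {
  arm_side <- match.arg(arm_side)
  cols <- sil_cols(sil, hip_row)
  if (length(cols) < 2L)
    stop("pose error: hip row nearly empty, arms not outstretched?",
         call. = FALSE)
  gaps <- which(diff(cols) > 1L)
  if (length(gaps) == 0L)
    stop("pose error: no arm/torso gap on the hip row", call. = FALSE)
  if (arm_side == "left") {
    cut <- cols[gaps[1]]               # last arm column before the first gap
    in_arm_cols <- seq_len(cut)
  } else {
    cut <- cols[gaps[length(gaps)] + 1L]  # first arm column after the last gap
    in_arm_cols <- seq.int(cut, ncol(sil$bits))
  }
  arm <- sil$bits[, in_arm_cols, drop = FALSE]
  arm_rows <- which(rowSums(arm) > 0L)
  arm_end <- max(arm_rows)
  wrist_row <- arm_end - head_height %/% 2L
  if (wrist_row < 1L)
    stop("pose error: wrist row above frame", call. = FALSE)
  wcols <- in_arm_cols[which(arm[wrist_row, ] == 1L)]
  if (length(wcols) == 0L)
    stop("pose error: empty wrist row in arm sub-region", call. = FALSE)
  wrist <- px_coord(wrist_row, round_half_up(mean(wcols)))
  elbow <- px_coord(round_half_up((wrist["row"] + shoulder["row"]) / 2),
                    round_half_up((wrist["col"] + shoulder["col"]) / 2))
  list(wrist = wrist, elbow = elbow)
}

joint_dist <- function(a, b) sqrt(sum((a - b)^2))

#' Calibrate the per-subject body model from the front-plane pose
#'
#' Runs the full front-pose chain on a single depth frame of the subject
#' standing about 3 m from the sensor, facing it with outstretched arms:
#' background subtraction, silhouette extraction, anthropometric joint
#' localization, and measurement of the five inter-joint pixel distances
#' (head-shoulder, shoulder-elbow, elbow-wrist, ankle-knee, knee-hip) that
#' drive side-view tracking.  The ratio `R` is computed in pixels as
#' silhouette height over head height and mapped to the hip coefficient `c`.
#'
#' @param df front-pose depth frame.
#' @param bf background frame from [build_background()].
#' @param intr a [depth_intrinsics()].
#' @param th foreground threshold (mm, default 150).
#' @param arm_side which image side holds the reference arm (default
#'   `"left"`, i.e. frame-left).
#' @return list of class `gait_calibration` with `model` (class `body_model`)
#'   and `joints` (named list of row/col coordinates: head, shoulder, elbow,
#'   wrist, hip, knee, ankle).
#' @export
#' @examples
#' cfg <- scene_config(noise_sigma = 0, dropout_rate = 0)
#' fig <- figure_config(stature_mm = 1700)
#' bg <- build_background(render_background(cfg, n_frames = 3))
#' fp <- render_person(cfg, fig, front_pose(), view = "front")
#' cal <- calibrate(fp$frame, bg, cfg$intrinsics)
#' cal$model
calibrate <- function(df, bf, intr = depth_intrinsics(), th = 150,
                      arm_side = c("left", "right")) {
  arm_side <- match.arg(arm_side)
  sil <- largest_silhouette(foreground_mask(df, bf, th))
  z <- subject_depth(df, sil)
  hh_sil <- human_height(sil)
  rmd <- find_row_max_dim(sil, z, intr)
  head <- locate_head_front(sil, rmd)
  hh_head <- head_height_px(sil, rmd, z, intr)
  R <- hh_sil / hh_head
  c_coef <- coefficient_c(R)
  shoulder <- locate_shoulder_front(sil, rmd, z, intr, arm_side = arm_side)
  hip_row <- locate_hip_row(sil, hh_head, c_coef)
  lower <- locate_ankle_knee_front(sil, z, intr)
  arm <- locate_arm_chain(sil, hip_row, hh_head, shoulder, arm_side)
  # hip column: centre of the torso = largest contiguous column run on the
  # hip row (both arms excluded)
  hcols <- sil_cols(sil, hip_row)
  runs <- split(hcols, cumsum(c(1L, diff(hcols) > 1L)))
  torso <- runs[[which.max(lengths(runs))]]
  hip <- px_coord(hip_row, round_half_up(mean(torso)))

  joints <- list(head = head$joint, shoulder = shoulder, elbow = arm$elbow,
                 wrist = arm$wrist, hip = hip, knee = lower$knee,
                 ankle = lower$ankle)
  model <- structure(list(
    human_height = hh_sil,
    head_height = hh_head,
    shift_row = head$shift_row,
    R = R,
    c = c_coef,
    hs_dist = max(1, joint_dist(head$joint, shoulder)),
    se_dist = max(1, joint_dist(shoulder, arm$elbow)),
    ew_dist = max(1, joint_dist(arm$elbow, arm$wrist)),
    ak_dist = max(1L, lower$ak_dist),   # a row shift, inherently integer
    kh_dist = max(1, joint_dist(lower$knee, hip)),
    subject_depth = z
  ), class = "body_model")
  structure(list(model = model, joints = joints), class = "gait_calibration")
}

#' @export
print.body_model <- function(x, ...) {
  cat("body_model:\n")
  cat(sprintf("  silhouette height %d px, head height %d px (R = %.2f, c = %.1f)\n",
              x$human_height, x$head_height, x$R, x$c))
  cat(sprintf("  distances (px): HS %.1f, SE %.1f, EW %.1f, AK %.0f, KH %.1f\n",
              x$hs_dist, x$se_dist, x$ew_dist, x$ak_dist, x$kh_dist))
  cat(sprintf("  head shift %d rows, subject depth %.0f mm\n",
              x$shift_row, x$subject_depth))
  invisible(x)
}

#' Write / read a body-model calibration file
#'
#' Key-value text format holding every calibrated quantity.
#'
#' @param model a `body_model` from [calibrate()].
#' @param path file path.
#' @return `path` invisibly / a `body_model`.
#' @export
write_body_model <- function(model, path) {
  write_config(unclass(model), path)
}

#' @rdname write_body_model
#' @export
read_body_model <- function(path) {
  x <- read_config(path)
  needed <- c("human_height", "head_height", "shift_row", "R", "c",
              "hs_dist", "se_dist", "ew_dist", "ak_dist", "kh_dist",
              "subject_depth")
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0L)
    stop("calibration file lacks fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  structure(x[needed], class = "body_model")
}
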