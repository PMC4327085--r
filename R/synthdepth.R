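# Synthetic depth scenes with exact joint ground truth.  A 2.5-D capsule
# figure (each body segment a constant-depth capsule projected through the
# pinhole model) stands in for the depth sensor: the tracking algorithm only
# consumes silhouettes and coarse depth gaps, so flat-depth capsules keep the
# ground truth exact while exercising every stage.

#' Scene configuration for the synthetic depth generator
#'
#' Defaults reproduce the reference test-room geometry: sensor 920 mm above
#' the floor, wall 3300 mm away, armless chair 300 mm in front of the wall.
#'
#' @param wall_depth wall distance from the sensor (mm).
#' @param sensor_height sensor height above the floor (mm).
#' @param chair_depth chair distance from the sensor (mm).
#' @param intrinsics a [depth_intrinsics()].
#' @param noise_sigma additive Gaussian depth-noise sd (mm, default 10).
#' @param dropout_rate per-pixel probability of a lost reading (0 value).
#' @return object of class `scene_config`.
#' @export
scene_config <- function(wall_depth = 3300, sensor_height = 920,
                         chair_depth = 3000, intrinsics = depth_intrinsics(),
                         noise_sigma = 10, dropout_rate = 0.005) {
  stopifnot(wall_depth > chair_depth, chair_depth > 0,
            dropout_rate >= 0, dropout_rate <= 1, noise_sigma >= 0)
  structure(list(wall_depth = wall_depth, sensor_height = sensor_height,
                 chair_depth = chair_depth, intrinsics = intrinsics,
                 noise_sigma = noise_sigma, dropout_rate = dropout_rate),
            class = "scene_config")
}

#' Figure configuration: a capsule human of given stature
#'
#' Segment lengths follow the anthropometric-survey proportions used by the
#' tracking model: head height is `stature / R` and the head-top-to-hip
#' distance `c` head heights for the chosen survey dataset (default 51);
#' the shank is 0.2 stature; arm segments use standard segment/stature
#' ratios.  Radii are capsule half-widths in mm.
#'
#' @param stature_mm total stature (mm).
#' @param dataset survey dataset id from [anthropometric_table()].
#' @param subject_depth depth of the subject plane for the front pose (mm).
#' @param near_offset_mm how much closer near-side limbs are than the trunk
#'   surface (default 85 mm: the near leg and arm read just outside the
#'   80-mm near-side gap of the trunk).
#' @param far_offset_mm how much deeper far-side limbs are than the trunk
#'   (default 35 mm; near and far limbs end up 120 mm apart).
#' @return object of class `figure_config` with all segment lengths (mm).
#' @export
figure_config <- function(stature_mm = 1700, dataset = 51L,
                          subject_depth = 3000, near_offset_mm = 85,
                          far_offset_mm = 35) {
  tab <- anthropometric_table()
  row <- tab[tab$dataset == dataset, ]
  if (nrow(row) != 1L) stop("unknown survey dataset: ", dataset, call. = FALSE)
  s <- stature_mm
  head_h <- s / row$ratio
  neck <- 100
  shoulder_h <- s - head_h - neck
  hip_h <- s - row$c * head_h
  ankle_h <- 70
  shank <- 0.2 * s
  knee_h <- ankle_h + shank
  structure(list(
    stature = s, dataset = dataset,
    head_h = head_h, neck = neck,
    shoulder_h = shoulder_h, hip_h = hip_h,
    ankle_h = ankle_h, knee_h = knee_h,
    shank = shank, thigh = hip_h - knee_h,
    trunk = shoulder_h - hip_h,
    shoulder_half = 0.122 * s,    # biacromial half-breadth
    gh_inset = 30, gh_drop = 60,  # glenohumeral centre vs acromion apex
    se_len = 0.186 * s - 60,      # glenohumeral centre to elbow
    ew_len = 0.146 * s,           # elbow to wrist
    hand = 100,                   # capsule hand (no finger geometry)
    leg_x = 100,                  # lateral half-stance, front view
    arm_angle_front = 70,         # arm depression below horizontal, front pose
    foot_len = 140,
    r_head = 0.36 * head_h, r_trunk_side = 120,
    r_shoulder_bar = 60, r_torso_front = 160,
    r_thigh = 55, r_shank = 45, r_foot = 30,
    r_upper_arm = 40, r_forearm = 30, r_hand = 30,
    subject_depth = subject_depth,
    near_offset = near_offset_mm,
    far_offset = far_offset_mm
  ), class = "figure_config")
}

# world (X lateral mm, Y height mm, Z depth mm) -> image (row, col), 1-based
world_to_px <- function(cfg, x, y, z) {
  intr <- cfg$intrinsics
  list(row = (intr$center_y + 1) - (y - cfg$sensor_height) * intr$focal_y / z,
       col = (intr$center_x + 1) + x * intr$focal_x / z)
}

# paint a constant-depth capsule into the depth matrix (min-depth wins)
draw_capsule <- function(depth, cfg, p0, p1, radius, z) {
  a <- world_to_px(cfg, p0[1], p0[2], z)
  b <- world_to_px(cfg, p1[1], p1[2], z)
  intr <- cfg$intrinsics
  rpx <- radius * max(intr$focal_x, intr$focal_y) / z
  r_lo <- max(1L, floor(min(a$row, b$row) - rpx))
  r_hi <- min(nrow(depth), ceiling(max(a$row, b$row) + rpx))
  c_lo <- max(1L, floor(min(a$col, b$col) - rpx))
  c_hi <- min(ncol(depth), ceiling(max(a$col, b$col) + rpx))
  if (r_lo > r_hi || c_lo > c_hi) return(depth)
  rows <- r_lo:r_hi; cols <- c_lo:c_hi
  rr <- matrix(rows, length(rows), length(cols))
  cc <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  # distance from each pixel to the projected segment
  vx <- b$row - a$row; vy <- b$col - a$col
  len2 <- vx^2 + vy^2
  if (len2 == 0) {
    d2 <- (rr - a$row)^2 + (cc - a$col)^2
  } else {
    t <- pmin(1, pmax(0, ((rr - a$row) * vx + (cc - a$col) * vy) / len2))
    d2 <- (rr - a$row - t * vx)^2 + (cc - a$col - t * vy)^2
  }
  hit <- d2 <= rpx^2
  blk <- depth[rows, cols]
  blk[hit & (blk == 0L | blk > z)] <- as.integer(round_half_up(z))
  depth[rows, cols] <- blk
  depth
}

# clean empty scene: wall, floor, chair side profile
render_scene_clean <- function(cfg) {
  intr <- cfg$intrinsics
  nr <- intr$height; nc <- intr$width
  depth <- matrix(as.integer(round_half_up(cfg$wall_depth)), nr, nc)
  # floor: rows looking down far enough that the floor is nearer than the wall
  rows <- seq_len(nr)
  drop_px <- rows - (intr$center_y + 1)   # pixels below the optical axis
  zfloor <- ifelse(drop_px > 0, cfg$sensor_height * intr$focal_y / drop_px, Inf)
  floor_rows <- which(zfloor < cfg$wall_depth)
  for (r in floor_rows)
    depth[r, ] <- as.integer(round_half_up(zfloor[r]))
  # armless chair, side profile at chair_depth: seat slab, backrest, two legs
  depth <- draw_capsule(depth, cfg, c(-1230, 440), c(-800, 440), 25,
                        cfg$chair_depth)                      # seat
  depth <- draw_capsule(depth, cfg, c(-1250, 460), c(-1250, 880), 30,
                        cfg$chair_depth)                      # backrest
  depth <- draw_capsule(depth, cfg, c(-1210, 40), c(-1210, 420), 20,
                        cfg$chair_depth)                      # rear leg
  depth <- draw_capsule(depth, cfg, c(-830, 40), c(-830, 420), 20,
                        cfg$chair_depth)                      # front leg
  depth_frame(depth)
}

#' Apply the sensor noise model to a clean depth frame
#'
#' Additive zero-mean Gaussian noise on valid pixels plus Bernoulli dropout
#' to 0 (lost reading).  A flat sigma approximates structured-light noise,
#' whose true magnitude grows with depth; see the methods vignette.
#'
#' @param frame clean depth frame.
#' @param sigma Gaussian sd (mm).
#' @param dropout_rate per-pixel dropout probability.
#' @return noisy [depth_frame()].
#' @export
add_depth_noise <- function(frame, sigma = 10, dropout_rate = 0.005) {
  out <- frame
  valid <- out > 0L
  if (sigma > 0)
    out[valid] <- pmax(1L, as.integer(round_half_up(
      out[valid] + rnorm(sum(valid), 0, sigma))))
  if (dropout_rate > 0) {
    drop <- valid & matrix(runif(length(out)) < dropout_rate,
                           nrow(out), ncol(out))
    out[drop] <- 0L
  }
  depth_frame(out)
}

#' Render the empty-scene background sequence
#'
#' @param cfg a [scene_config()].
#' @param n_frames number of frames (default 100, the reference protocol).
#' @return a [frame_sequence()] of noisy copies of the clean scene.
#' @export
render_background <- function(cfg = scene_config(), n_frames = 100L) {
  clean <- render_scene_clean(cfg)
  frame_sequence(lapply(seq_len(n_frames), function(i)
    add_depth_noise(clean, cfg$noise_sigma, cfg$dropout_rate)))
}

#' Front-pose specification
#'
#' The calibration stance: facing the sensor, arms outstretched downward-
#' outward at the configured depression angle so a column gap separates each
#' arm from the torso at hip level.
#'
#' @param pelvis_x lateral position of the body midline (mm).
#' @return object of class `pose_spec`.
#' @export
front_pose <- function(pelvis_x = 600) {
  structure(list(view = "front", pelvis_x = pelvis_x), class = "pose_spec")
}

#' Side-view pose specification
#'
#' Sagittal-plane joint angles, degrees from vertical, positive toward the
#' walking direction (+X, frame right).  The pelvis height is derived from
#' the leg chain so the lower foot rests on the floor.
#'
#' @param pelvis_x pelvis lateral position (mm).
#' @param trunk_lean trunk forward lean.
#' @param thigh,shank numeric length-2 (near, far) absolute segment angles.
#' @param arm,elbow_flex numeric length-2 (near, far) upper-arm angle and
#'   elbow flexion.
#' @param body_depth trunk depth (mm).
#' @return object of class `pose_spec`.
#' @export
side_pose <- function(pelvis_x = 0, trunk_lean = 3,
                      thigh = c(0, 0), shank = c(0, 0),
                      arm = c(5, 5), elbow_flex = c(15, 15),
                      body_depth = 3000) {
  structure(list(view = "side", pelvis_x = pelvis_x, trunk_lean = trunk_lean,
                 thigh = thigh, shank = shank, arm = arm,
                 elbow_flex = elbow_flex, body_depth = body_depth),
            class = "pose_spec")
}

deg <- function(a) a * pi / 180

# side-view skeleton in world coordinates for a pose
side_skeleton <- function(fig, pose) {
  th_t <- deg(pose$thigh); th_s <- deg(pose$shank)
  drop_leg <- pmax(fig$thigh * cos(th_t[1]) + fig$shank * cos(th_s[1]),
                   fig$thigh * cos(th_t[2]) + fig$shank * cos(th_s[2]))
  pelvis <- c(pose$pelvis_x, fig$ankle_h + drop_leg)
  lean <- deg(pose$trunk_lean)
  trunk_dir <- c(sin(lean), cos(lean))
  trunk_top <- pelvis + fig$trunk * trunk_dir
  head_c <- trunk_top + (fig$neck + fig$head_h / 2) * trunk_dir
  leg <- function(i) {
    knee <- pelvis + fig$thigh * c(sin(th_t[i]), -cos(th_t[i]))
    ankle <- knee + fig$shank * c(sin(th_s[i]), -cos(th_s[i]))
    list(knee = knee, ankle = ankle)
  }
  arm <- function(i) {
    a <- deg(pose$arm[i]); f <- deg(pose$elbow_flex[i])
    elbow <- trunk_top + fig$se_len * c(sin(a), -cos(a))
    wrist <- elbow + fig$ew_len * c(sin(a + f), -cos(a + f))
    hand <- wrist + fig$hand * c(sin(a + f), -cos(a + f))
    list(elbow = elbow, wrist = wrist, hand = hand)
  }
  list(pelvis = pelvis, trunk_top = trunk_top, head_c = head_c,
       near_leg = leg(1), far_leg = leg(2),
       near_arm = arm(1), far_arm = arm(2))
}

#' Render one frame of the capsule figure over the scene
#'
#' Each body segment is a constant-depth capsule projected through the
#' pinhole model onto the clean scene; near-side limbs are rendered closer
#' to the sensor than the trunk, far-side limbs deeper, so near and far
#' limbs are separated by twice the configured offset (100 mm by default).
#' Returns the clean (noise-free) frame and the exact projected joint
#' coordinates; callers add noise via [add_depth_noise()].
#'
#' @param cfg a [scene_config()].
#' @param fig a [figure_config()].
#' @param pose a [front_pose()] or [side_pose()].
#' @param view `"front"` or `"side"` (must match the pose).
#' @return list with `frame` (clean [depth_frame()]) and `joints` (named list
#'   of 1-based row/col ground-truth coordinates; front view also includes
#'   `wrist`).
#' @export
render_person <- function(cfg, fig, pose, view = c("front", "side")) {
  view <- match.arg(view)
  if (!identical(pose$view, view))
    stop("pose/view mismatch", call. = FALSE)
  depth <- unclass(render_scene_clean(cfg))
  if (view == "front") {
    z <- fig$subject_depth
    x0 <- pose$pelvis_x
    s <- fig
    # trunk: shoulder bar + tapering torso + pelvis bar
    bar_y <- s$shoulder_h - s$r_shoulder_bar
    depth <- draw_capsule(depth, cfg,
                          c(x0 - (s$shoulder_half - s$r_shoulder_bar), bar_y),
                          c(x0 + (s$shoulder_half - s$r_shoulder_bar), bar_y),
                          s$r_shoulder_bar, z)
    depth <- draw_capsule(depth, cfg, c(x0, s$shoulder_h - 90),
                          c(x0, s$hip_h + 80), s$r_torso_front, z)
    depth <- draw_capsule(depth, cfg, c(x0 - 60, s$hip_h + 20),
                          c(x0 + 60, s$hip_h + 20), 90, z)
    # head + neck
    depth <- draw_capsule(depth, cfg, c(x0, s$stature - s$r_head),
                          c(x0, s$stature - s$head_h + s$r_head), s$r_head, z)
    depth <- draw_capsule(depth, cfg, c(x0, s$stature - s$head_h),
                          c(x0, s$shoulder_h), 50, z)
    # arms from the glenohumeral centres, depressed below horizontal
    al <- deg(s$arm_angle_front)
    gh_y <- s$shoulder_h - s$gh_drop
    gh_x <- s$shoulder_half - s$gh_inset
    joints <- list()
    for (sgn in c(-1, 1)) {
      gh <- c(x0 + sgn * gh_x, gh_y)
      dir <- c(sgn * cos(al), -sin(al))
      elbow <- gh + s$se_len * dir
      wrist <- elbow + s$ew_len * dir
      hand <- wrist + s$hand * dir
      depth <- draw_capsule(depth, cfg, gh, elbow, s$r_upper_arm, z)
      depth <- draw_capsule(depth, cfg, elbow, wrist, s$r_forearm, z)
      depth <- draw_capsule(depth, cfg, wrist, hand, s$r_hand, z)
      if (sgn == -1) {  # frame-left arm is the calibration reference
        joints$shoulder <- gh; joints$elbow <- elbow; joints$wrist <- wrist
      }
    }
    # legs (left = frame-left chain is the reference)
    for (sgn in c(-1, 1)) {
      hip <- c(x0 + sgn * s$leg_x, s$hip_h)
      knee <- c(x0 + sgn * s$leg_x, s$knee_h)
      ankle <- c(x0 + sgn * s$leg_x, s$ankle_h)
      depth <- draw_capsule(depth, cfg, hip, knee, s$r_thigh, z)
      depth <- draw_capsule(depth, cfg, knee, ankle, s$r_shank, z)
      depth <- draw_capsule(depth, cfg, c(x0 + sgn * s$leg_x - 40, 40),
                            c(x0 + sgn * s$leg_x + 40, 40), 35, z)
      if (sgn == -1) {
        joints$hip <- hip; joints$knee <- knee; joints$ankle <- ankle
      }
    }
    joints$head <- c(x0, s$stature - s$head_h / 2)
    gt <- lapply(joints, function(p) {
      px <- world_to_px(cfg, p[1], p[2], z)
      px_coord(round_half_up(px$row), round_half_up(px$col))
    })
    gt <- gt[c("head", "shoulder", "elbow", "wrist", "hip", "knee", "ankle")]
    return(list(frame = depth_frame(depth), joints = gt))
  }

  # side view
  z <- pose$body_depth
  zn <- z - fig$near_offset
  zf <- z + fig$far_offset
  sk <- side_skeleton(fig, pose)
  # far limbs first (min-depth makes order irrelevant, kept for clarity)
  for (side in c("far", "near")) {
    zl <- if (side == "near") zn else zf
    za <- if (side == "near") z - fig$near_offset - 10 else zf
    lg <- sk[[paste0(side, "_leg")]]
    ar <- sk[[paste0(side, "_arm")]]
    depth <- draw_capsule(depth, cfg, sk$pelvis, lg$knee, fig$r_thigh, zl)
    depth <- draw_capsule(depth, cfg, lg$knee, lg$ankle, fig$r_shank, zl)
    depth <- draw_capsule(depth, cfg, c(lg$ankle[1], 40),
                          c(lg$ankle[1] + fig$foot_len, 30), fig$r_foot, zl)
    depth <- draw_capsule(depth, cfg, sk$trunk_top, ar$elbow,
                          fig$r_upper_arm, za)
    depth <- draw_capsule(depth, cfg, ar$elbow, ar$wrist, fig$r_forearm, za)
    depth <- draw_capsule(depth, cfg, ar$wrist, ar$hand, fig$r_hand, za)
  }
  depth <- draw_capsule(depth, cfg, sk$pelvis, sk$trunk_top,
                        fig$r_trunk_side, z)
  hd <- (sk$head_c - sk$trunk_top) / sqrt(sum((sk$head_c - sk$trunk_top)^2))
  depth <- draw_capsule(depth, cfg,
                        sk$head_c - (fig$head_h / 2 - fig$r_head) * hd,
                        sk$head_c + (fig$head_h / 2 - fig$r_head) * hd,
                        fig$r_head, z)
  world <- list(head = sk$head_c, shoulder = sk$trunk_top,
                elbow = sk$near_arm$elbow, hip = sk$pelvis,
                knee = sk$near_leg$knee, ankle = sk$near_leg$ankle)
  zs <- c(head = z, shoulder = z, elbow = zn, hip = z, knee = zn, ankle = zn)
  gt <- lapply(names(world), function(nm) {
    p <- world[[nm]]
    px <- world_to_px(cfg, p[1], p[2], zs[[nm]])
    px_coord(round_half_up(px$row), round_half_up(px$col))
  })
  names(gt) <- names(world)
  list(frame = depth_frame(depth), joints = gt)
}

ease <- function(u) (1 - cos(pi * pmin(1, pmax(0, u)))) / 2  # smooth 0..1

# pose schedule for the Get Up and Go Test: seated -> rising -> walking
gugt_pose_at <- function(fig, u, t, duration, x_start = -1100,
                         body_depth = 3000, walk_speed = 700,
                         stride_hz = 0.9) {
  seated_thigh <- 80; seated_shank <- 20
  x_feet <- x_start + fig$thigh * sin(deg(seated_thigh)) +
    fig$shank * sin(deg(seated_shank))
  if (u < 0.25) {                      # seated, ready: arms hanging at the side
    side_pose(pelvis_x = x_start, trunk_lean = 5,
              thigh = c(seated_thigh, seated_thigh),
              shank = c(seated_shank, seated_shank),
              arm = c(5, 5), elbow_flex = c(8, 8),
              body_depth = body_depth)
  } else if (u < 0.45) {               # rising
    s <- ease((u - 0.25) / 0.20)
    side_pose(pelvis_x = x_start + s * (x_feet - x_start),
              trunk_lean = 5 + 23 * sin(pi * s),
              thigh = rep(seated_thigh * (1 - s), 2),
              shank = rep(seated_shank * (1 - s), 2),
              arm = c(5, 5), elbow_flex = c(8 + 7 * s, 8 + 7 * s),
              body_depth = body_depth)
  } else {                             # walking
    tw <- t - 0.45 * duration          # seconds since walk onset
    ph <- 2 * pi * stride_hz * tw
    flex <- function(p) 20 * (1 + cos(p + 0.8 * pi)) / 2
    th_n <- 25 * sin(ph); th_f <- 25 * sin(ph + pi)
    side_pose(pelvis_x = x_feet + walk_speed * tw,
              trunk_lean = 5 + 2 * sin(2 * ph),
              thigh = c(th_n, th_f),
              shank = c(th_n - flex(ph), th_f - flex(ph + pi)),
              arm = c(5 - 15 * sin(ph), 5 + 15 * sin(ph)),
              elbow_flex = c(15, 15),
              body_depth = body_depth)
  }
}

#' Simulate a Get Up and Go Test depth sequence with ground truth
#'
#' Seated (25% of frames), rising (20%), then walking across the frame at
#' constant depth, 30 fps.  Deterministic given `seed`; noise follows the
#' scene configuration.
#'
#' @param cfg a [scene_config()].
#' @param fig a [figure_config()].
#' @param n_frames number of frames (default 120, i.e. 4 s).
#' @param seed integer seed for the noise model.
#' @return list with `frames` (a [frame_sequence()]), `truth` (a
#'   [joint_trajectory()] of exact projected joint positions) and `phases`
#'   (character vector: seated / rising / walking).
#' @export
#' @examples
#' sim <- simulate_gugt(scene_config(), figure_config(), n_frames = 4, seed = 1)
#' sim$truth
simulate_gugt <- function(cfg = scene_config(), fig = figure_config(),
                          n_frames = 120L, seed = 1L) {
  if (n_frames < 2L) stop("n_frames must be >= 2", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  frames <- vector("list", n_frames)
  coords <- array(NA_real_, dim = c(n_frames, 6L, 2L))
  phases <- character(n_frames)
  for (i in seq_len(n_frames)) {
    u <- (i - 1) / (n_frames - 1)
    t <- (i - 1) / 30
    pose <- gugt_pose_at(fig, u, t, duration = (n_frames - 1) / 30)
    phases[i] <- if (u < 0.25) "seated" else if (u < 0.45) "rising" else "walking"
    rp <- render_person(cfg, fig, pose, view = "side")
    frames[[i]] <- add_depth_noise(rp$frame, cfg$noise_sigma, cfg$dropout_rate)
    for (j in seq_along(JOINTS))
      coords[i, j, ] <- rp$joints[[JOINTS[j]]]
  }
  list(frames = frame_sequence(frames), truth = joint_trajectory(coords),
       phases = phases)
}
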