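test_that("raster_segment is 8-connected, endpoint-inclusive and matches the oracle", {
  set.seed(51)
  for (i in 1:120) {
    p <- round(runif(4, 1, 60))
    px <- raster_segment(p[1], p[2], p[3], p[4])
    expect_equal(px[1, ], c(row = p[1], col = p[2]), ignore_attr = TRUE)
    expect_equal(px[nrow(px), ], c(row = p[3], col = p[4]),
                 ignore_attr = TRUE)
    if (nrow(px) > 1) {
      steps <- abs(diff(px))
      expect_true(all(steps <= 1))                 # 8-connected
      expect_true(all(rowSums(steps) >= 1))        # no repeated pixel
    }
    expect_identical(unname(px), unname(naive_raster(p[1], p[2], p[3], p[4])))
  }
})

test_that("locate_head_side reuses the calibrated shift", {
  m <- matrix(0L, 240, 320); m[26:200, 120:180] <- 1L
  m[36, ] <- 0L; m[36, 141:161] <- 1L
  sil <- silhouette(m)
  model <- list(shift_row = 10)
  h <- locate_head_side(sil, model)
  expect_equal(unname(h), c(36, 151))
  model$shift_row <- 300
  expect_error(locate_head_side(sil, model), "tracking error")
})

test_that("locate_shoulder_side re-projects to the calibrated length", {
  m <- matrix(0L, 240, 320); m[20:200, 140:160] <- 1L
  sil <- silhouette(m)
  model <- list(hs_dist = 30)
  head <- c(row = 40, col = 150)
  sh <- locate_shoulder_side(sil, head, model)
  # provisional is straight below the head -> shifted down exactly hs_dist
  expect_equal(unname(sh), c(70, 150))
  # provisional pulled diagonally (extra pixels widen the provisional row):
  # the final estimate keeps the direction but re-scales to hs_dist
  m2 <- matrix(0L, 240, 320)
  m2[20:200, 140:160] <- 1L
  m2[70, 161:220] <- 1L     # provisional col -> (140 + 220) / 2 = 180
  sil2 <- silhouette(m2)
  sh2 <- locate_shoulder_side(sil2, c(row = 40, col = 150), model)
  d <- sqrt(sum((sh2 - c(40, 150))^2))
  expect_lt(abs(d - 30), 1)
  dir <- (sh2 - c(40, 150)) / d
  want <- c(30, 30) / sqrt(1800)
  expect_lt(max(abs(dir - want)), 0.06)
})

test_that("near_side_region keeps only depths within the gap of the near limb", {
  bits <- matrix(0L, 240, 320)
  bits[100:220, 100:110] <- 1L   # near leg
  bits[100:220, 130:140] <- 1L   # far leg
  df <- matrix(3300L, 240, 320)
  df[100:220, 100:110] <- 2500L
  df[100:220, 130:140] <- 2650L
  sil <- silhouette(bits)
  model <- list(ak_dist = 30L)
  reg <- near_side_region(depth_frame(df), sil, model)
  expect_true(all(reg$bits[, 100:110] == sil$bits[, 100:110]))
  expect_true(all(reg$bits[, 130:140] == 0L))       # 150 mm away: excluded
  expect_lt(abs(reg$reference_depth - 2500), 15)

  # single uniform leg: region is the whole leg
  one <- matrix(0L, 240, 320); one[100:220, 100:110] <- 1L
  dfo <- matrix(3300L, 240, 320); dfo[one == 1L] <- 2500L
  rego <- near_side_region(depth_frame(dfo), silhouette(one), model)
  expect_identical(unclass(rego$bits), one, ignore_attr = TRUE)

  # a lone 200-mm noise spike at the window centre is rejected by the
  # windowed outlier test and the near leg is still recovered
  dfs <- dfo
  r <- 220 - 15
  cmin <- 105
  dfs[r, cmin] <- 2300L   # spike becomes the minimal-depth seed
  regs <- near_side_region(depth_frame(dfs), silhouette(one), model)
  expect_gt(sum(regs$bits), 0.9 * sum(one))
  expect_lt(abs(regs$reference_depth - 2500), 25)
})

test_that("rotating elbow fit finds a straight-down arm", {
  df <- matrix(3300L, 240, 320)
  sil_bits <- matrix(0L, 240, 320)
  # torso column + arm hanging straight down from the shoulder
  sil_bits[40:200, 140:170] <- 1L
  df[sil_bits == 1L] <- 2900L
  arm_rows <- 80:140; arm_cols <- 146:154
  df[arm_rows, arm_cols] <- 2800L   # arm 100 mm nearer
  sil <- silhouette(sil_bits)
  model <- list(se_dist = 40)
  sh <- c(row = 80, col = 150)
  el <- locate_elbow_side(depth_frame(df), sil, sh, model)
  expect_equal(unname(el["col"]), 150, tolerance = 2)
  expect_equal(unname(el["row"]), 120, tolerance = 2)
})

test_that("rotating fits break ties toward the smaller angle", {
  bits <- matrix(1L, 100, 100)   # every angle overlaps fully
  fit <- depthgait:::rotating_fit(bits, c(row = 50, col = 50), 20,
                                  angles = seq(2, 178, 2),
                                  dir_fun = function(a)
                                    c(sin(a * pi / 180), cos(a * pi / 180)))
  expect_equal(fit$angle, 2)
})

test_that("locate_knee_side re-projects to ak_dist from the ankle", {
  reg <- list(bits = matrix(0L, 240, 320))
  reg$bits[100:220, 145:155] <- 1L   # vertical shank
  model <- list(ak_dist = 35L)
  ankle <- c(row = 210, col = 150)
  kn <- locate_knee_side(reg, ankle, model)
  expect_equal(unname(kn), c(175, 150))
  # flexed shank at ~30 degrees: distance still ak_dist within 1 px
  reg2 <- list(bits = matrix(0L, 240, 320))
  for (i in 0:120) {
    r <- 220 - i
    ccol <- 150 + round(i * 0.58)
    reg2$bits[r, max(1, ccol - 4):(ccol + 4)] <- 1L
  }
  kn2 <- locate_knee_side(reg2, c(row = 220, col = 150), model)
  expect_lt(abs(sqrt(sum((kn2 - c(220, 150))^2)) - 35), 1)
  empty <- list(bits = matrix(0L, 240, 320))
  expect_error(locate_knee_side(empty, ankle, model), "tracking error")
})

test_that("hip fit follows the thigh orientation", {
  model <- list(kh_dist = 40)
  # upright: vertical thigh above the knee
  reg <- list(bits = matrix(0L, 240, 320))
  reg$bits[60:180, 145:155] <- 1L
  hip <- locate_hip_side(reg, c(row = 170, col = 150), model)
  expect_equal(unname(hip["col"]), 150, tolerance = 2)
  expect_equal(unname(hip["row"]), 130, tolerance = 2)
  # seated: horizontal thigh, hip displaced horizontally by kh_dist
  reg2 <- list(bits = matrix(0L, 240, 320))
  reg2$bits[165:175, 60:160] <- 1L
  hip2 <- locate_hip_side(reg2, c(row = 170, col = 150), model)
  expect_equal(unname(hip2["row"]), 170, tolerance = 3)
  expect_equal(unname(hip2["col"]), 110, tolerance = 3)
  # knee-hip distance equals kh_dist by construction
  expect_lt(abs(sqrt(sum((hip2 - c(170, 150))^2)) - 40), 1)
  empty <- list(bits = matrix(0L, 240, 320))
  expect_error(locate_hip_side(empty, c(row = 170, col = 150), model),
               "tracking error")
})

test_that("tracked head-shoulder and ankle-knee distances honour the model", {
  traj <- fx_traj()
  model <- fx_cal()$model
  co <- traj$coords
  hs <- sqrt(rowSums((co[, "head", ] - co[, "shoulder", ])^2))
  ak <- sqrt(rowSums((co[, "ankle", ] - co[, "knee", ])^2))
  expect_true(all(abs(hs - model$hs_dist) <= 1, na.rm = TRUE))
  expect_true(all(abs(ak - model$ak_dist) <= 1, na.rm = TRUE))
})

test_that("tracking is deterministic and handles degenerate sequences", {
  seq2 <- frame_sequence(fx_sim0()$frames$frames[1:2])
  t1 <- track_sequence(seq2, fx_bg0(), fx_cal0()$model, fx_scene0()$intrinsics)
  t2 <- track_sequence(seq2, fx_bg0(), fx_cal0()$model, fx_scene0()$intrinsics)
  expect_identical(t1$coords, t2$coords)
  # identical frames give identical joint sets
  same <- frame_sequence(list(seq2$frames[[1]], seq2$frames[[1]]))
  ts <- track_sequence(same, fx_bg0(), fx_cal0()$model, fx_scene0()$intrinsics)
  expect_identical(ts$coords[1, , ], ts$coords[2, , ])
  # background-only frames -> everything missing
  bonly <- frame_sequence(list(fx_bg0(), fx_bg0()))
  tb <- track_sequence(bonly, fx_bg0(), fx_cal0()$model,
                       fx_scene0()$intrinsics)
  expect_true(all(is.na(tb$coords)))
})

test_that("noise-free tracking stays close to ground truth on a GUGT", {
  st <- diff_statistics(fx_traj0(), fx_sim0()$truth, compensate = TRUE)
  mus <- setNames(st$summary$mu, st$summary$joint)
  expect_true(all(mus <= 8), info = paste(round(mus, 2), collapse = " "))
  expect_equal(names(which.max(mus)), "hip")
})

test_that("sigma = 10 mm depth noise degrades accuracy by at most 3 px", {
  # same 30-frame schedule, noisy scene vs noise-free scene
  sim_n <- simulate_gugt(fx_scene(), fx_fig(), n_frames = 30, seed = 5)
  traj_n <- track_sequence(sim_n$frames, fx_bg(), fx_cal()$model,
                           fx_scene()$intrinsics)
  st_n <- diff_statistics(traj_n, sim_n$truth, compensate = TRUE)$summary
  st_0 <- diff_statistics(fx_traj0(), fx_sim0()$truth,
                          compensate = TRUE)$summary
  expect_true(all(st_n$mu - st_0$mu <= 3))
})

test_that("trajectories round-trip through CSV with missing markers", {
  co <- array(NA_real_, dim = c(4, 6, 2))
  co[, , 1] <- matrix(10 + 1:24, 4, 6)
  co[, , 2] <- matrix(50 + 1:24, 4, 6)
  co[2, 3, ] <- NA   # one missing joint-frame
  traj <- joint_trajectory(co)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  d <- read.csv(path)
  expect_identical(names(d), c("frame", "joint", "row", "col", "missing"))
  # missing rows carry the 0 sentinel plus flag
  miss <- d[d$missing == 1L, ]
  expect_equal(nrow(miss), 1L)
  expect_equal(miss$row, 0)
  back <- read_trajectory(path)
  expect_equal(back$coords, traj$coords)
})

test_that("interpolation fills interior gaps only", {
  co <- array(NA_real_, dim = c(5, 6, 2))
  co[, 1, 1] <- c(NA, 10, NA, 30, NA)
  co[, 1, 2] <- c(NA, 100, NA, 120, NA)
  traj <- interpolate_trajectory(joint_trajectory(co))
  expect_equal(traj$coords[3, 1, ], c(row = 20, col = 110),
               ignore_attr = TRUE)
  expect_true(is.na(traj$coords[1, 1, 1]))
  expect_true(is.na(traj$coords[5, 1, 1]))
})
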