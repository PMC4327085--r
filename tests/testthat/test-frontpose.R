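test_that("survey ratios and coefficients reproduce the printed table", {
  tab <- anthropometric_table()
  # datasets with self-consistent printed rows (8's S-BH cell and 51's R are
  # known print inconsistencies and excluded from the respective checks)
  # agreement at each value's printed precision (dataset 20 prints one
  # decimal, 7.9; the rest two)
  for (d in c(10L, 7L, 9L, 21L, 20L)) {
    r <- tab[tab$dataset == d, ]
    expect_true(matches_printed(table1_ratio(r$stature, r$head_height),
                                r$ratio),
                info = paste("ratio, dataset", d))
  }
  for (d in c(10L, 7L, 9L, 51L, 21L, 20L)) {
    r <- tab[tab$dataset == d, ]
    expect_equal(table1_coefficient(r$stature, r$buttock_height,
                                    r$head_height), r$c,
                 info = paste("c, dataset", d))
  }
  expect_equal(table1_ratio(5, 5), 1)
  expect_equal(table1_coefficient(100, 50, 50), 1)
  expect_error(table1_ratio(160, 0), "head_height")
  expect_error(table1_coefficient(80, 90, 22), "stature")
})

test_that("coefficient_c reproduces all six branches with closed left edges", {
  expect_equal(coefficient_c(6.0), 3.2)
  expect_equal(coefficient_c(7.15), 3.4)
  expect_equal(coefficient_c(9.0), 4.2)
  # boundary values belong to the upper branch
  expect_equal(coefficient_c(c(6.4, 7.2, 7.5, 8, 8.8)),
               c(3.4, 3.6, 3.8, 4, 4.2))
  expect_equal(coefficient_c(c(6.39, 7.19, 7.49, 7.99, 8.79)),
               c(3.2, 3.4, 3.6, 3.8, 4))
  # piecewise-constant, monotone, exactly six levels
  r <- seq(1, 15, by = 0.01)
  v <- coefficient_c(r)
  expect_true(all(diff(v) >= 0))
  expect_identical(sort(unique(v)), c(3.2, 3.4, 3.6, 3.8, 4, 4.2))
  expect_error(coefficient_c(0), "R")
})

test_that("human_height subtracts silhouette row extremes", {
  m <- matrix(0L, 240, 320); m[21:220, 100:120] <- 1L
  expect_equal(human_height(silhouette(m)), 199)
  m1 <- matrix(0L, 10, 10); m1[4, 2:8] <- 1L
  expect_equal(human_height(silhouette(m1)), 0)
})

test_that("find_row_max_dim finds the widening row", {
  intr <- depth_intrinsics()
  z <- 2856  # 10 px per 100 mm, step = 4 px
  # T-shape: narrow head (width 20) then wide shoulders (width 80) at row 61
  m <- matrix(0L, 240, 320)
  m[11:60, 151:170] <- 1L
  m[61:190, 121:200] <- 1L
  sil <- silhouette(m)
  rmd <- find_row_max_dim(sil, z, intr)
  # scan starts at 11 + 10 = 21, samples every 4 rows: widening caught at the
  # first sampled row at/below 61 -> 61
  expect_equal(rmd, 61)

  # constant-width rectangle: all differences zero, topmost sampled row wins
  r <- matrix(0L, 240, 320); r[11:190, 151:170] <- 1L
  expect_equal(find_row_max_dim(silhouette(r), z, intr), 21)

  # widths strictly decreasing then a +60 jump at row 57 (inside the scanned
  # upper third): the sampled row at the jump wins
  w <- matrix(0L, 240, 320)
  for (row in 11:56) w[row, 151:(170 - (row - 11) %/% 10)] <- 1L
  w[57:190, 121:200] <- 1L
  expect_equal(find_row_max_dim(silhouette(w), z, intr), 57)

  short <- matrix(0L, 240, 320); short[11:20, 151:170] <- 1L
  expect_error(find_row_max_dim(silhouette(short), z, intr), "calibration")
})

test_that("locate_head_front applies the one-third shift rule", {
  m <- matrix(0L, 240, 320)
  m[31:100, 151:171] <- 1L
  sil <- silhouette(m)
  res <- locate_head_front(sil, row_max_dim = 61)
  expect_equal(res$shift_row, 10)        # (61 - 31) %/% 3
  expect_equal(unname(res$joint["row"]), 41)
  expect_equal(unname(res$joint["col"]), 161)  # midpoint of 151 and 171
  expect_error(locate_head_front(sil, 31), "calibration")
})

test_that("head height subtracts the neck allowance", {
  intr <- depth_intrinsics()
  m <- matrix(0L, 240, 320); m[11:200, 100:200] <- 1L
  sil <- silhouette(m)
  # 100 mm at 2856 mm is 10 px; span 45 px -> 35 px
  expect_equal(head_height_px(sil, 11 + 45, 2856, intr), 35)
  expect_error(head_height_px(sil, 11 + 10, 2856, intr), "calibration")
})

test_that("locate_shoulder_front shifts 40 mm down and 40 mm inboard", {
  intr <- depth_intrinsics()
  z <- 2856  # 40 mm = 4 px
  m <- matrix(0L, 240, 320); m[11:200, 101:200] <- 1L
  sil <- silhouette(m)
  sh <- locate_shoulder_front(sil, row_max_dim = 60, z, intr)
  expect_equal(unname(sh), c(64, 105))
  sh_r <- locate_shoulder_front(sil, 60, z, intr, arm_side = "right")
  expect_equal(unname(sh_r), c(64, 196))
  # a shift landing outside the silhouette is a calibration error
  narrow <- matrix(0L, 240, 320); narrow[11:200, 101:103] <- 1L
  expect_error(locate_shoulder_front(silhouette(narrow), 60, z, intr),
               "calibration")
})

test_that("hip row and ankle/knee placement follow the printed coefficients", {
  intr <- depth_intrinsics()
  m <- matrix(0L, 240, 320); m[21:220, 140:180] <- 1L
  sil <- silhouette(m)
  expect_equal(locate_hip_row(sil, head_height = 30, c = 3.4), 20 + 102 + 1)
  expect_equal(locate_hip_row(sil, head_height = 0, c = 3.4), 21)
  expect_error(locate_hip_row(sil, 100, 4.2), "calibration")

  z <- 2856
  lower <- locate_ankle_knee_front(sil, z, intr)
  # human height 199 -> ak_dist = round(0.2 * 199) = 40
  expect_equal(lower$ak_dist, 40L)
  expect_equal(unname(lower$ankle["row"]), 220 - 4)
  expect_equal(unname(lower$knee["row"]), 216 - 40)
  expect_equal(unname(lower$ankle["col"]), 160)
})

test_that("locate_arm_chain finds the wrist through the column gap", {
  m <- matrix(0L, 240, 320)
  m[21:200, 140:180] <- 1L   # torso
  m[60:150, 100:110] <- 1L   # separated vertical arm bar, ends at row 150
  sil <- silhouette(m)
  res <- locate_arm_chain(sil, hip_row = 120, head_height = 30,
                          shoulder = c(row = 60, col = 144))
  expect_equal(unname(res$wrist["row"]), 150 - 15)
  expect_equal(unname(res$wrist["col"]), 105)
  # elbow is the exact midpoint of wrist and shoulder
  expect_equal(unname(res$elbow["row"]),
               floor((135 + 60) / 2 + 0.5))
  expect_equal(unname(res$elbow["col"]),
               floor((105 + 144) / 2 + 0.5))
  # shoulder == wrist degenerate midpoint
  res2 <- locate_arm_chain(sil, 120, 30, c(row = 135, col = 105))
  expect_equal(unname(res2$elbow), c(135, 105))
  # no gap on the hip row -> pose error
  solid <- matrix(0L, 240, 320); solid[21:200, 100:180] <- 1L
  expect_error(locate_arm_chain(silhouette(solid), 120, 30,
                                c(row = 60, col = 144)), "pose error")
})

test_that("calibration recovers segment lengths on a rendered figure", {
  cal <- fx_cal0()
  fp <- render_person(fx_scene0(), fx_fig(), front_pose(), view = "front")
  gt <- fp$joints
  seg <- function(a, b) sqrt(sum((gt[[a]] - gt[[b]])^2))
  want <- c(hs_dist = seg("head", "shoulder"),
            se_dist = seg("shoulder", "elbow"),
            ew_dist = seg("elbow", "wrist"),
            ak_dist = seg("ankle", "knee"),
            kh_dist = seg("knee", "hip"))
  for (d in names(want))
    expect_lt(abs(cal$model[[d]] - want[[d]]) / want[[d]], 0.10, label = d)
  expect_true(cal$model$c %in% c(3.2, 3.4, 3.6, 3.8, 4, 4.2))
  expect_gt(cal$model$R, 0)
  # every located joint inside the silhouette bounding box
  for (j in cal$joints) {
    expect_gte(j[["row"]], 1); expect_lte(j[["row"]], 240)
    expect_gte(j[["col"]], 1); expect_lte(j[["col"]], 320)
  }
})

test_that("calibrated distances scale with subject depth", {
  # deeper wall so the far render stays clear of the background threshold
  cfg <- scene_config(wall_depth = 3700, noise_sigma = 0, dropout_rate = 0)
  bg <- build_background(render_background(cfg, n_frames = 1))
  fig_near <- figure_config(1700, subject_depth = 2800)
  fig_far <- figure_config(1700, subject_depth = 3200)
  cal_n <- calibrate(render_person(cfg, fig_near, front_pose(),
                                   "front")$frame, bg, cfg$intrinsics)
  cal_f <- calibrate(render_person(cfg, fig_far, front_pose(),
                                   "front")$frame, bg, cfg$intrinsics)
  # pinhole scaling: distances shrink by the depth ratio, within ~1.5 px of
  # quantization per endpoint
  for (d in c("hs_dist", "se_dist", "ew_dist", "ak_dist", "kh_dist")) {
    expect_lt(abs(cal_n$model[[d]] * 2800 / 3200 - cal_f$model[[d]]), 3,
              label = d)
  }
  expect_equal(cal_n$model$subject_depth, 2800, tolerance = 0.02)
})

test_that("calibrate fails cleanly with no subject", {
  bf <- fx_bg0()
  expect_error(calibrate(bf, bf, fx_scene0()$intrinsics), "no subject")
})

test_that("body model round-trips through the calibration file", {
  path <- withr::local_tempfile(fileext = ".txt")
  model <- fx_cal0()$model
  write_body_model(model, path)
  back <- read_body_model(path)
  for (f in names(unclass(model)))
    expect_equal(back[[f]], model[[f]], label = f)
  writeLines("human_height = 100", path)
  expect_error(read_body_model(path), "lacks fields")
})
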