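# Shared synthetic fixtures, built once per test run and memoized: rendering
# a 120-frame sequence is the expensive part of the suite.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fx)) assign(key, force(expr), envir = .fx)
  get(key, envir = .fx)
}

fx_scene <- function() memo("scene", scene_config())
fx_scene0 <- function() memo("scene0",
                             scene_config(noise_sigma = 0, dropout_rate = 0))
fx_fig <- function() memo("fig", figure_config(1700))

fx_bg <- function() memo("bg", {
  set.seed(42)
  build_background(render_background(fx_scene(), n_frames = 30))
})
fx_bg0 <- function() memo("bg0",
  build_background(render_background(fx_scene0(), n_frames = 2)))

fx_cal <- function() memo("cal", {
  set.seed(43)
  fp <- render_person(fx_scene(), fx_fig(), front_pose(), view = "front")
  calibrate(add_depth_noise(fp$frame, 10, 0.005), fx_bg(),
            fx_scene()$intrinsics)
})
fx_cal0 <- function() memo("cal0", {
  fp <- render_person(fx_scene0(), fx_fig(), front_pose(), view = "front")
  calibrate(fp$frame, fx_bg0(), fx_scene0()$intrinsics)
})

fx_sim <- function() memo("sim",
  simulate_gugt(fx_scene(), fx_fig(), n_frames = 120, seed = 7))
fx_traj <- function() memo("traj",
  track_sequence(fx_sim()$frames, fx_bg(), fx_cal()$model,
                 fx_scene()$intrinsics))

# small noise-free sequence for per-frame locator tests
fx_sim0 <- function() memo("sim0",
  simulate_gugt(fx_scene0(), fx_fig(), n_frames = 30, seed = 1))
fx_traj0 <- function() memo("traj0",
  track_sequence(fx_sim0()$frames, fx_bg0(), fx_cal0()$model,
                 fx_scene0()$intrinsics))

# naive flood-fill component labelling (oracle for the C++ implementation)
naive_label <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8L)
    cbind(c(-1,-1,-1,0,0,1,1,1), c(-1,0,1,-1,1,-1,0,1))
  else cbind(c(-1,0,0,1), c(0,-1,1,0))
  cur <- 0L
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (mask[r, cc] != 0L && lab[r, cc] == 0L) {
      cur <- cur + 1L
      queue <- list(c(r, cc)); lab[r, cc] <- cur
      while (length(queue) > 0L) {
        p <- queue[[1]]; queue <- queue[-1]
        for (k in seq_len(nrow(nb))) {
          r2 <- p[1] + nb[k, 1]; c2 <- p[2] + nb[k, 2]
          if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
              mask[r2, c2] != 0L && lab[r2, c2] == 0L) {
            lab[r2, c2] <- cur
            queue[[length(queue) + 1L]] <- c(r2, c2)
          }
        }
      }
    }
  }
  lab
}

# naive scalar rounded-parametric integer line (oracle for raster_segment):
# endpoints rounded to the pixel grid, then one step per major-axis pixel
naive_raster <- function(r0, c0, r1, c1) {
  r0 <- floor(r0 + 0.5); c0 <- floor(c0 + 0.5)
  r1 <- floor(r1 + 0.5); c1 <- floor(c1 + 0.5)
  n <- max(abs(r1 - r0), abs(c1 - c0))
  out <- matrix(0L, n + 1L, 2L)
  for (i in 0:n) {
    out[i + 1L, 1L] <- as.integer(floor(r0 +
      (if (n == 0) 0 else i * (r1 - r0) / n) + 0.5))
    out[i + 1L, 2L] <- as.integer(floor(c0 +
      (if (n == 0) 0 else i * (c1 - c0) / n) + 0.5))
  }
  out
}

# agreement at the precision a value was printed with (e.g. 7.9 vs 7.90625)
matches_printed <- function(x, printed) {
  dec <- nchar(sub("^[^.]*\\.?", "", format(printed, trim = TRUE)))
  abs(x - printed) <= 0.5 * 10^(-dec) + 1e-12
}

rand_mask <- function(nr, nc, p = 0.4) {
  matrix(as.integer(runif(nr * nc) < p), nr, nc)
}

make_traj <- function(coords) joint_trajectory(coords)
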