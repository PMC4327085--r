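# Trajectory validation: Euclidean per-frame differences against a reference
# track (marker-based or synthetic ground truth), least-squares offset
# compensation, and occlusion-aware mean/sd summaries.

#' Euclidean distance between an estimated and a reference joint position
#'
#' @param est,ref named row/col coordinate vectors; `NA` components mark a
#'   missing observation.
#' @return distance in px, or `NA` when either side is missing.
#' @export
joint_difference <- function(est, ref) {
  if (anyNA(est) || anyNA(ref)) return(NA_real_)
  sqrt((est[["row"]] - ref[["row"]])^2 + (est[["col"]] - ref[["col"]])^2)
}

# frames where both tracks observe joint j
jointly_present <- function(traj, ref, j) {
  !is.na(traj$coords[, j, 1]) & !is.na(traj$coords[, j, 2]) &
    !is.na(ref$coords[, j, 1]) & !is.na(ref$coords[, j, 2])
}

#' Remove the constant offset between a trajectory and its reference
#'
#' Per joint, subtracts the constant 2-D offset that minimizes the sum of
#' squared differences over jointly observed frames -- i.e. the mean
#' coordinate difference (the least-squares solution for a pure translation).
#' Missing frames are excluded from the fit and preserved in the output.
#'
#' @param traj estimated [joint_trajectory()].
#' @param ref reference `joint_trajectory` of the same length.
#' @return the compensated trajectory.
#' @export
compensate_offset <- function(traj, ref) {
  if (dim(traj$coords)[1] != dim(ref$coords)[1])
    stop("trajectory and reference lengths differ", call. = FALSE)
  coords <- traj$coords
  for (j in seq_len(dim(coords)[2])) {
    ok <- jointly_present(traj, ref, j)
    if (!any(ok))
      stop("validation error: no overlapping frames for joint ",
           traj$joints[j], call. = FALSE)
    off_r <- mean(coords[ok, j, 1] - ref$coords[ok, j, 1])
    off_c <- mean(coords[ok, j, 2] - ref$coords[ok, j, 2])
    coords[, j, 1] <- coords[, j, 1] - off_r
    coords[, j, 2] <- coords[, j, 2] - off_c
  }
  joint_trajectory(coords)
}

#' Per-joint difference series and summary statistics
#'
#' Builds the per-frame Euclidean difference series for each joint and its
#' mean and standard deviation.  Frames where either track is missing
#' (occluded marker, failed locator) are excluded from mu and sigma; sigma is
#' the sample (n - 1) standard deviation.
#'
#' @param traj estimated [joint_trajectory()].
#' @param ref reference `joint_trajectory` of the same length.
#' @param compensate remove the per-joint constant offset first (default
#'   `TRUE`, increasing the relevance of the statistics).
#' @return object of class `diff_statistics`: list with `summary` (data.frame
#'   `joint, mu, sigma, n`) and `series` (K x 6 matrix of distances, `NA` for
#'   excluded frames).  Joints with no evaluable frame get `NA` statistics.
#' @export
#' @examples
#' a <- joint_trajectory(array(1, dim = c(4, 6, 2)))
#' b <- joint_trajectory(array(2, dim = c(4, 6, 2)))
#' diff_statistics(a, b, compensate = FALSE)$summary
diff_statistics <- function(traj, ref, compensate = TRUE) {
  if (dim(traj$coords)[1] != dim(ref$coords)[1])
    stop("trajectory and reference lengths differ", call. = FALSE)
  if (compensate) traj <- compensate_offset(traj, ref)
  k <- dim(traj$coords)[1]
  series <- matrix(NA_real_, k, 6L, dimnames = list(NULL, traj$joints))
  for (j in seq_len(6L)) {
    ok <- jointly_present(traj, ref, j)
    dr <- traj$coords[ok, j, 1] - ref$coords[ok, j, 1]
    dc <- traj$coords[ok, j, 2] - ref$coords[ok, j, 2]
    series[ok, j] <- sqrt(dr^2 + dc^2)
  }
  summary <- data.frame(
    joint = traj$joints,
    mu = apply(series, 2, function(v) if (all(is.na(v))) NA_real_
                                      else mean(v, na.rm = TRUE)),
    sigma = apply(series, 2, function(v) if (sum(!is.na(v)) < 2L) NA_real_
                                         else sd(v, na.rm = TRUE)),
    n = colSums(!is.na(series)),
    row.names = NULL
  )
  structure(list(summary = summary, series = series),
            class = "diff_statistics")
}

#' @export
print.diff_statistics <- function(x, ...) {
  cat("Per-joint trajectory differences vs reference (px):\n")
  s <- x$summary
  cat(sprintf("  %-9s %8s %8s %6s\n", "joint", "mu", "sigma", "n"))
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-9s %8.4f %8.4f %6d\n",
                s$joint[i], s$mu[i], s$sigma[i], s$n[i]))
  invisible(x)
}

#' Detect bright markers in an intensity frame
#'
#' Stand-in detector for validation against synthetic marker layouts:
#' thresholds the frame, labels 8-connected blobs, and returns one centroid
#' per blob, assigned to joints top-to-bottom (head first).  When fewer blobs
#' than expected are found, the lowest joints are flagged occluded (`NA`).
#'
#' @param ir 2-D intensity matrix (markers brighter than background).
#' @param intensity_threshold minimum marker intensity.
#' @param expected_count number of markers / joints (default 6).
#' @return data.frame `joint, row, col` (`NA` rows for occluded joints);
#'   joint names follow the head-to-ankle vertical layout.
#' @export
detect_markers <- function(ir, intensity_threshold, expected_count = 6L) {
  mask <- matrix(as.integer(ir >= intensity_threshold), nrow(ir), ncol(ir))
  joints <- if (expected_count == 6L) JOINTS
            else paste0("marker", seq_len(expected_count))
  out <- data.frame(joint = joints, row = NA_real_, col = NA_real_)
  if (!any(mask == 1L)) return(out)
  labels <- .label_components_cpp(mask, 8L)
  nblob <- max(labels)
  cent <- t(vapply(seq_len(nblob), function(b) {
    idx <- which(labels == b, arr.ind = TRUE)
    c(mean(idx[, 1]), mean(idx[, 2]))
  }, numeric(2)))
  cent <- cent[order(cent[, 1]), , drop = FALSE]  # top to bottom
  take <- min(nblob, expected_count)
  out$row[seq_len(take)] <- cent[seq_len(take), 1]
  out$col[seq_len(take)] <- cent[seq_len(take), 2]
  out
}
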