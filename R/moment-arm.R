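#' Tendon line of action from superficial/deep edge points
#'
#' The superficial and deep tendon edges identified in an ultrasound
#' image (probe frame) are paired; each pair's midpoint is a point on the
#' tendon's central line. Midpoints are transformed from the probe frame
#' to the shank frame through the two cluster poses, and the line of
#' action is the total-least-squares line through them (first principal
#' direction of the midpoint cloud).
#'
#' @param superficial,deep m x 3 matrices of matched edge points in the
#'   probe frame (m >= 2).
#' @param probe_pose,shank_pose `rigid_pose` of the probe and shank
#'   clusters in the lab frame; pass NULL for both if the edge points are
#'   already in the shank frame.
#' @return object of class `tendon_line`: unit `direction`, `point` (the
#'   midpoint centroid, mm, shank frame), `rms_mm` off-line scatter.
#' @export
fit_tendon_line <- function(superficial, deep, probe_pose = NULL,
                            shank_pose = NULL) {
  superficial <- matrix(superficial, ncol = 3)
  deep <- matrix(deep, ncol = 3)
  if (nrow(superficial) < 2 || nrow(deep) < 2) {
    stop("need at least 2 superficial and 2 deep edge points")
  }
  if (nrow(superficial) != nrow(deep)) {
    stop("superficial and deep edge points must be paired")
  }
  mid <- (superficial + deep) / 2
  if (!is.null(probe_pose)) {
    mid <- pose_apply(probe_pose, mid)          # probe -> lab
  }
  if (!is.null(shank_pose)) {
    mid <- pose_apply(pose_invert(shank_pose), mid)  # lab -> shank
  }
  ctr <- colMeans(mid)
  X <- sweep(mid, 2, ctr)
  if (max(abs(X)) < 1e-12) stop("all midpoints coincide; no line defined")
  sv <- svd(X)
  dir <- unitize(sv$v[, 1])
  resid <- X - (X %*% dir) %*% t(dir)
  structure(list(direction = dir, point = ctr,
                 rms_mm = sqrt(mean(rowSums(resid^2)))),
            class = "tendon_line")
}

#' Moment arm as the perpendicular distance between two 3-D lines
#'
#' The Achilles tendon moment arm is the common-perpendicular (skew-line)
#' distance between the tendon line of action and the functional rotation
#' axis, both expressed in the shank frame:
#' `|(p1 - p2) . (d1 x d2)| / ||d1 x d2||`. For (near-)parallel lines the
#' distance falls back to the point-to-line distance, which is the exact
#' limit. Symmetric in its two arguments.
#'
#' @param line,axis objects with unit `direction` and `point` fields
#'   (a `tendon_line` and a `functional_axis`, in either order).
#' @return distance in the input length unit (mm).
#' @export
compute_moment_arm <- function(line, axis) {
  d1 <- unitize(line$direction)
  d2 <- unitize(axis$direction)
  cr <- cross3(d1, d2)
  dp <- line$point - axis$point
  if (vnorm(cr) < 1e-10) {
    # parallel: distance from a point of one line to the other line
    return(vnorm(dp - sum(dp * d2) * d2))
  }
  abs(sum(dp * cr)) / vnorm(cr)
}

#' Quadratic moment-arm-vs-angle fit and the neutral (0 deg) estimate
#'
#' Ordinary least-squares quadratic of moment arm against ankle angle
#' over the observed range; the constant coefficient is the moment arm at
#' the 0 deg (neutral) posture.
#'
#' @param angles_deg ankle angles (degrees, dorsiflexion positive,
#'   0 = neutral); must include or bracket 0 deg within 5 deg.
#' @param moment_arms_mm per-frame moment arms (mm).
#' @return object of class `moment_arm_curve`: `coefficients`
#'   (c0 mm, c1 mm/deg, c2 mm/deg^2), `moment_arm_0deg_mm` (= c0),
#'   `frames` data.frame(angle_deg, moment_arm_mm), `r_squared`.
#' @export
moment_arm_at_neutral <- function(angles_deg, moment_arms_mm) {
  stopifnot(length(angles_deg) == length(moment_arms_mm))
  if (length(angles_deg) < 5) stop("need at least 5 frames")
  if (length(unique(angles_deg)) < 3) {
    stop("need at least 3 distinct angles for a quadratic fit")
  }
  if (min(angles_deg) > 5 || max(angles_deg) < -5) {
    stop("angle range must include or bracket 0 deg within 5 deg")
  }
  X <- cbind(1, angles_deg, angles_deg^2)
  fit <- stats::lm.fit(X, moment_arms_mm)
  cf <- unname(fit$coefficients)
  sst <- sum((moment_arms_mm - mean(moment_arms_mm))^2)
  r2 <- if (sst > 0) 1 - sum(fit$residuals^2) / sst else NA_real_
  structure(list(coefficients = c(c0 = cf[1], c1 = cf[2], c2 = cf[3]),
                 moment_arm_0deg_mm = cf[1],
                 frames = data.frame(angle_deg = angles_deg,
                                     moment_arm_mm = moment_arms_mm),
                 r_squared = r2),
            class = "moment_arm_curve")
}

#' @export
print.moment_arm_curve <- function(x, ...) {
  cat("moment_arm_curve: ", nrow(x$frames), " frames, moment arm at 0 deg = ",
      round(x$moment_arm_0deg_mm, 2), " mm\n", sep = "")
  invisible(x)
}

#' End-to-end moment-arm analysis of a range-of-motion trial
#'
#' Runs the full chain on a trial (as produced by [generate_rom_trial()]
#' or read by [read_rom_trial()]): per-frame cluster poses for shank,
#' foot, and probe; foot-in-shank poses; best-fit functional axis; signed
#' ankle angle per frame; per-frame tendon line from the edge points;
#' per-frame moment arm as the line-axis distance; and the quadratic
#' neutral-posture estimate.
#'
#' @param trial a `rom_trial` object.
#' @return list with `axis` (`functional_axis`), `frames` (data.frame:
#'   angle_deg, moment_arm_mm), `curve` (`moment_arm_curve`), and
#'   `moment_arm_0deg_mm`.
#' @export
analyze_rom_trial <- function(trial) {
  nf <- length(trial$frames)
  shank <- lapply(trial$frames, function(f) {
    fit_rigid_pose(trial$references$shank, f$shank)
  })
  foot <- lapply(trial$frames, function(f) {
    fit_rigid_pose(trial$references$foot, f$foot)
  })
  probe <- lapply(trial$frames, function(f) {
    fit_rigid_pose(trial$references$probe, f$probe)
  })
  foot_in_shank <- lapply(seq_len(nf), function(i) {
    pose_compose(pose_invert(shank[[i]]), foot[[i]])
  })
  axis <- fit_functional_axis(foot_in_shank)
  # orient the axis so dorsiflexion (motion toward the trial's most
  # dorsiflexed pose) is positive
  angles <- pose_angles_about_axis(foot_in_shank, axis)
  if (!is.null(trial$dorsiflexion_frame) &&
      angles[trial$dorsiflexion_frame] < 0) {
    axis$direction <- -axis$direction
    angles <- -angles
  }
  ma <- vapply(seq_len(nf), function(i) {
    line <- fit_tendon_line(trial$frames[[i]]$superficial,
                            trial$frames[[i]]$deep,
                            probe_pose = probe[[i]],
                            shank_pose = shank[[i]])
    compute_moment_arm(line, axis)
  }, 1.0)
  curve <- moment_arm_at_neutral(angles, ma)
  list(axis = axis,
       frames = data.frame(angle_deg = angles, moment_arm_mm = ma),
       curve = curve,
       moment_arm_0deg_mm = curve$moment_arm_0deg_mm)
}
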