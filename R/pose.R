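#' Least-squares rigid pose from matched marker clusters
#'
#' Finds the proper rigid transform (rotation + translation, no
#' reflection) minimizing the sum of squared distances
#' `sum ||R ref_i + t - obs_i||^2` over matched marker pairs, via the
#' SVD of the cross-covariance (Kabsch). Used to express marker clusters
#' on the shank, foot, and ultrasound transducer in a common frame.
#'
#' @param reference n x 3 matrix of marker positions in the segment's
#'   reference (calibration) configuration.
#' @param observed n x 3 matrix of the same markers observed in the
#'   target frame, row-matched to `reference`.
#' @return object of class `rigid_pose`: `R` (3 x 3 proper rotation),
#'   `t` (length-3 translation), `rms` residual (same units as input).
#' @export
fit_rigid_pose <- function(reference, observed) {
  reference <- as.matrix(reference)
  observed <- as.matrix(observed)
  if (!all(dim(reference) == dim(observed))) {
    stop("reference and observed marker sets must have matching dimensions")
  }
  n <- nrow(reference)
  if (n < 3) stop("at least 3 markers are required")
  cr <- colMeans(reference)
  co <- colMeans(observed)
  P <- sweep(reference, 2, cr)
  Q <- sweep(observed, 2, co)
  sv_ref <- svd(P)$d
  if (sv_ref[2] < 1e-9 * max(sv_ref[1], 1)) {
    stop("markers are collinear; the pose is not identifiable")
  }
  H <- t(P) %*% Q
  sv <- svd(H)
  S <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% S %*% t(sv$u)
  t <- as.numeric(co - R %*% cr)
  res <- observed - (reference %*% t(R) + matrix(t, n, 3, byrow = TRUE))
  structure(list(R = R, t = t, rms = sqrt(mean(rowSums(res^2)))),
            class = "rigid_pose")
}

#' Compose and invert rigid poses
#' @noRd
pose_compose <- function(a, b) {
  # (a o b)(x) = a(b(x))
  structure(list(R = a$R %*% b$R, t = as.numeric(a$R %*% b$t + a$t),
                 rms = NA_real_), class = "rigid_pose")
}

#' @noRd
pose_invert <- function(p) {
  structure(list(R = t(p$R), t = as.numeric(-t(p$R) %*% p$t),
                 rms = NA_real_), class = "rigid_pose")
}

#' @noRd
pose_apply <- function(p, pts) {
  pts <- matrix(pts, ncol = 3)
  pts %*% t(p$R) + matrix(p$t, nrow(pts), 3, byrow = TRUE)
}

#' Finite helical (screw) axis of a relative rigid displacement
#'
#' Decomposes the displacement taking frame i to frame j into a rotation
#' about, and translation along, a unique axis.
#'
#' @param R_rel,t_rel relative rotation and translation (x -> R x + t).
#' @return list: unit `direction`, `point` on the axis (the point closest
#'   to the origin), `angle_deg`, `translation` along the axis.
#' @keywords internal
helical_axis <- function(R_rel, t_rel) {
  aa <- rotation_axis_angle(R_rel)
  if (aa$angle_deg < 1e-9) {
    stop("relative rotation is (near) zero; helical axis undefined")
  }
  n <- aa$axis
  d <- sum(n * t_rel)
  t_perp <- t_rel - d * n
  th <- aa$angle_deg * pi / 180
  point <- 0.5 * (t_perp + cross3(n, t_perp) / tan(th / 2))
  list(direction = n, point = point, angle_deg = aa$angle_deg,
       translation = d)
}

#' Best-fit functional (screw) axis from a sequence of poses
#'
#' Reduces foot-in-shank poses recorded over a range-of-motion trial to a
#' single functional rotation axis: finite helical axes are computed
#' between all pose pairs spanning at least `min_pair_deg` of rotation
#' (smaller displacements give noise-dominated axes), their directions
#' are sign-aligned and averaged weighted by rotation magnitude, and the
#' axis point is the least-squares point closest to all the individual
#' helical axes. Weighting by rotation magnitude lets the wide-spanning
#' pairs, whose helical axes are least noise-sensitive, dominate the
#' average.
#'
#' @param poses list of `rigid_pose` objects (foot relative to shank).
#' @param min_pair_deg minimum rotation between paired poses (degrees).
#' @return object of class `functional_axis`: unit `direction`, `point`
#'   (mm, shank frame), `rms_mm` scatter of the helical axes about the
#'   fitted axis, `n_pairs`, `span_deg` total rotation span.
#' @export
fit_functional_axis <- function(poses, min_pair_deg = 5) {
  if (length(poses) < 2) stop("need at least 2 poses")
  # total span: largest relative rotation between any pose and the first
  angs <- vapply(poses, function(p) {
    rotation_axis_angle(p$R %*% t(poses[[1]]$R))$angle_deg
  }, 1.0)
  span <- max(angs)
  if (span < min_pair_deg) {
    stop("insufficient range of motion: rotation span ",
         round(span, 2), " deg < ", min_pair_deg, " deg")
  }
  pairs <- list()
  np <- length(poses)
  for (i in seq_len(np - 1)) {
    for (j in (i + 1):np) {
      rel_ang <- rotation_axis_angle(poses[[j]]$R %*%
                                       t(poses[[i]]$R))$angle_deg
      if (rel_ang >= min_pair_deg) {
        pairs[[length(pairs) + 1]] <- c(i, j)
      }
    }
  }
  if (length(pairs) == 0) stop("insufficient range of motion: no pose pair spans ",
                               min_pair_deg, " deg")
  if (length(pairs) > 2000) {
    pairs <- pairs[round(seq(1, length(pairs), length.out = 2000))]
  }
  has <- lapply(pairs, function(ij) {
    pi_ <- poses[[ij[1]]]
    pj <- poses[[ij[2]]]
    R_rel <- pj$R %*% t(pi_$R)
    t_rel <- pj$t - as.numeric(R_rel %*% pi_$t)
    helical_axis(R_rel, t_rel)
  })
  w <- vapply(has, `[[`, 1.0, "angle_deg")
  dirs <- t(vapply(has, `[[`, numeric(3), "direction"))
  # sign-align to the first direction before averaging
  for (k in seq_len(nrow(dirs))) {
    if (sum(dirs[k, ] * dirs[1, ]) < 0) {
      dirs[k, ] <- -dirs[k, ]
    }
  }
  direction <- unitize(colSums(dirs * w))
  # least-squares point: minimize sum w_k | (I - n_k n_k^T)(p - c_k) |^2
  A <- matrix(0, 3, 3)
  b <- numeric(3)
  for (k in seq_along(has)) {
    nk <- has[[k]]$direction
    Pk <- diag(3) - tcrossprod(nk)
    A <- A + w[k] * Pk
    b <- b + w[k] * as.numeric(Pk %*% has[[k]]$point)
  }
  # the component of the point along the common direction is
  # unconstrained (rank-2 system for a pure hinge); pin it to the
  # weighted mean axial position of the helical-axis points
  cpts <- t(vapply(has, `[[`, numeric(3), "point"))
  ax_pos <- sum(w * (cpts %*% direction)) / sum(w)
  A <- A + sum(w) * tcrossprod(direction)
  b <- b + sum(w) * direction * ax_pos
  point <- as.numeric(solve(A, b))
  dists <- vapply(seq_along(has), function(k) {
    v <- point - has[[k]]$point
    vnorm(v - sum(v * has[[k]]$direction) * has[[k]]$direction)
  }, 1.0)
  structure(list(direction = direction, point = point,
                 rms_mm = sqrt(stats::weighted.mean(dists^2, w)),
                 n_pairs = length(has), span_deg = span),
            class = "functional_axis")
}

#' Signed rotation angles of poses about a functional axis
#'
#' The ankle angle of each frame is the rotation of its pose relative to
#' the neutral calibration pose, signed by the component of the rotation
#' axis along the functional axis direction. With the axis oriented so
#' that dorsiflexion is positive, 0 deg is the neutral pose.
#'
#' @param poses list of `rigid_pose` (foot in shank).
#' @param axis a `functional_axis`.
#' @param neutral `rigid_pose` defining 0 deg (default: identity, i.e.
#'   the calibration configuration the poses are expressed against).
#' @return numeric vector of angles in degrees.
#' @export
pose_angles_about_axis <- function(poses, axis, neutral = NULL) {
  Rn <- if (is.null(neutral)) diag(3) else neutral$R
  vapply(poses, function(p) {
    aa <- rotation_axis_angle(p$R %*% t(Rn))
    if (aa$angle_deg < 1e-12 || any(is.na(aa$axis))) return(0)
    aa$angle_deg * sign(sum(aa$axis * axis$direction))
  }, 1.0)
}
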