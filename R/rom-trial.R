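#' Marker-cluster geometries used by the synthetic trials
#' @noRd
default_clusters <- function() {
  list(shank = rbind(c(0, 0, 0), c(80, 0, 10), c(40, 70, -10), c(20, 30, 60)),
       foot = rbind(c(0, 0, 0), c(90, 10, 0), c(45, 60, 15), c(30, 20, -40)),
       probe = rbind(c(0, 0, 0), c(50, 0, 5), c(25, 45, 0), c(15, 15, 35)))
}

#' Generate a synthetic ankle range-of-motion trial
#'
#' Emulates the moment-arm measurement protocol: the ankle is rotated
#' from maximum dorsiflexion to maximum plantarflexion about a known
#' hinge axis while marker clusters on shank, foot, and ultrasound probe
#' are tracked and the tendon's superficial and deep edges are digitized
#' in the probe frame. At each frame the tendon line is constructed so
#' that its perpendicular distance to the axis equals the prescribed
#' quadratic moment-arm curve evaluated at that frame's angle, making the
#' true neutral-posture moment arm exactly `quad_coeffs[1]`.
#'
#' @param axis list with `point` (mm) and `direction` in the shank frame;
#'   direction oriented so positive rotation is dorsiflexion.
#' @param tendon_line_spec list with `direction` (tendon line of action
#'   in the shank frame) and `half_thickness_mm` (edge offset from the
#'   midline).
#' @param quad_coeffs c(c0, c1, c2): moment arm (mm) = c0 + c1 a + c2 a^2
#'   with a the ankle angle in degrees.
#' @param marker_noise_sd iid Gaussian noise on marker coordinates (mm).
#' @param edge_noise_sd iid Gaussian noise on edge points (mm).
#' @param angles_deg the swept ankle angles, one frame each; must cover
#'   at least \[-15, +15\] deg.
#' @param n_edge_pairs superficial/deep pairs digitized per frame.
#' @param seed integer seed for the noise stream.
#' @return object of class `rom_trial`: `references` (cluster marker
#'   geometries), `frames` (per frame: observed shank/foot/probe markers
#'   in the lab frame, superficial/deep edge points in the probe frame,
#'   time), `dorsiflexion_frame`, and `truth` (axis, quadratic, angles).
#' @export
generate_rom_trial <- function(axis,
                               tendon_line_spec = list(
                                 direction = c(0.05, 0.1, 1),
                                 half_thickness_mm = 2.5),
                               quad_coeffs = c(46, -0.1, -0.01),
                               marker_noise_sd = 0,
                               edge_noise_sd = marker_noise_sd,
                               angles_deg = seq(20, -25, by = -0.5),
                               n_edge_pairs = 6,
                               seed = 1L) {
  if (vnorm(axis$direction) < 1e-12) stop("degenerate axis: zero direction")
  d_axis <- unitize(axis$direction)
  p_axis <- as.numeric(axis$point)
  if (min(angles_deg) > -15 || max(angles_deg) < 15) {
    stop("angle sweep must cover at least [-15, +15] deg")
  }
  d_line <- unitize(tendon_line_spec$direction)
  if (vnorm(cross3(d_line, d_axis)) < 1e-9) {
    stop("tendon line direction must not be parallel to the axis")
  }
  u <- unitize(cross3(d_line, d_axis))   # common-perpendicular direction
  w <- unitize(cross3(d_line, u))        # edge-offset direction
  half <- tendon_line_spec$half_thickness_mm
  clusters <- default_clusters()
  # fixed segment placements in the lab/shank world
  shank_base <- list(R = diag(3), t = c(0, 0, 300))
  probe_in_shank <- structure(list(R = rotation_about_axis(c(1, 1, 0), 15),
                                   t = c(20, 60, 80), rms = NA_real_),
                              class = "rigid_pose")
  offsets <- seq(-25, 25, length.out = n_edge_pairs)

  nf <- length(angles_deg)
  frames <- vector("list", nf)
  with_seed(seed, {
    for (i in seq_len(nf)) {
      a <- angles_deg[i]
      # slow rigid drift of the whole shank in the lab
      drift_ang <- 3 * sin(2 * pi * i / nf)
      shank_pose <- structure(
        list(R = rotation_about_axis(c(0.3, 1, 0.1), drift_ang) %*% shank_base$R,
             t = shank_base$t + c(2 * cos(2 * pi * i / nf), 0.5 * i / nf, 0),
             rms = NA_real_), class = "rigid_pose")
      Rf <- rotation_about_axis(d_axis, a)
      foot_in_shank <- structure(
        list(R = Rf, t = as.numeric(p_axis - Rf %*% p_axis), rms = NA_real_),
        class = "rigid_pose")
      foot_pose <- pose_compose(shank_pose, foot_in_shank)
      probe_pose <- pose_compose(shank_pose, probe_in_shank)

      ma <- quad_coeffs[1] + quad_coeffs[2] * a + quad_coeffs[3] * a^2
      p_line <- p_axis + ma * u
      pts_shank <- matrix(p_line, n_edge_pairs, 3, byrow = TRUE) +
        outer(offsets, d_line)
      pts_probe <- pose_apply(pose_invert(probe_in_shank), pts_shank)
      sup <- pts_probe + matrix(half * as.numeric(
        pose_invert(probe_in_shank)$R %*% w), n_edge_pairs, 3, byrow = TRUE)
      deep <- pts_probe - matrix(half * as.numeric(
        pose_invert(probe_in_shank)$R %*% w), n_edge_pairs, 3, byrow = TRUE)
      if (edge_noise_sd > 0) {
        sup <- sup + matrix(stats::rnorm(length(sup), 0, edge_noise_sd),
                            nrow(sup))
        deep <- deep + matrix(stats::rnorm(length(deep), 0, edge_noise_sd),
                              nrow(deep))
      }
      obs <- list(shank = pose_apply(shank_pose, clusters$shank),
                  foot = pose_apply(foot_pose, clusters$foot),
                  probe = pose_apply(probe_pose, clusters$probe))
      if (marker_noise_sd > 0) {
        obs <- lapply(obs, function(m) {
          m + matrix(stats::rnorm(length(m), 0, marker_noise_sd), nrow(m))
        })
      }
      frames[[i]] <- list(time = (i - 1) / 30, shank = obs$shank,
                          foot = obs$foot, probe = obs$probe,
                          superficial = sup, deep = deep)
    }
  })
  structure(list(references = clusters, frames = frames,
                 dorsiflexion_frame = which.max(angles_deg),
                 truth = list(axis = list(point = p_axis,
                                          direction = d_axis),
                              quad_coeffs = quad_coeffs,
                              angles_deg = angles_deg)),
            class = "rom_trial")
}

#' Write a range-of-motion trial to TSV + JSON sidecar
#'
#' One TSV row per frame: time, then x/y/z for each cluster marker
#' (`shank1_x` ...), then paired superficial/deep edge-point coordinates
#' in the probe frame (`sup1_x`, `deep1_x`, ...). Cluster reference
#' geometries and metadata go to a JSON sidecar `<prefix>_refs.json`.
#'
#' @param trial a `rom_trial`.
#' @param prefix output path prefix.
#' @return paths written, invisibly.
#' @export
write_rom_trial <- function(trial, prefix) {
  rows <- lapply(trial$frames, function(f) {
    flat <- function(m, nm) {
      v <- as.numeric(t(m))
      stats::setNames(v, paste0(rep(paste0(nm, seq_len(nrow(m))), each = 3),
                                c("_x", "_y", "_z")))
    }
    c(time = f$time, flat(f$shank, "shank"), flat(f$foot, "foot"),
      flat(f$probe, "probe"), flat(f$superficial, "sup"),
      flat(f$deep, "deep"))
  })
  df <- as.data.frame(do.call(rbind, rows))
  tsv <- paste0(prefix, "_frames.tsv")
  utils::write.table(df, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  js <- paste0(prefix, "_refs.json")
  jsonlite::write_json(list(references = trial$references,
                            dorsiflexion_frame = trial$dorsiflexion_frame),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}

#' Read a range-of-motion trial written by [write_rom_trial()]
#' @param prefix path prefix used when writing.
#' @return a `rom_trial` (without ground truth).
#' @export
read_rom_trial <- function(prefix) {
  df <- utils::read.delim(paste0(prefix, "_frames.tsv"))
  meta <- jsonlite::read_json(paste0(prefix, "_refs.json"),
                              simplifyVector = TRUE)
  refs <- lapply(meta$references, function(m) matrix(unlist(m), ncol = 3))
  take <- function(row, nm) {
    cols <- grep(paste0("^", nm, "[0-9]+_"), names(df), value = TRUE)
    matrix(as.numeric(row[cols]), ncol = 3, byrow = TRUE)
  }
  frames <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    list(time = row$time, shank = take(row, "shank"), foot = take(row, "foot"),
         probe = take(row, "probe"), superficial = take(row, "sup"),
         deep = take(row, "deep"))
  })
  structure(list(references = refs, frames = frames,
                 dorsiflexion_frame = meta$dorsiflexion_frame,
                 truth = NULL),
            class = "rom_trial")
}
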