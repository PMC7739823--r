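#' Generate a synthetic treadmill gait trial with a known torque waveform
#'
#' Constructs a per-cycle ankle plantarflexion torque waveform with a
#' single late-stance peak, then back-computes ground reaction force and
#' center-of-pressure series that are dynamically consistent with it
#' under the same sagittal-plane foot model the inverse dynamics uses, so
#' that event detection + inverse dynamics is a round trip. The foot is
#' kept quasi-static (fixed ankle joint center and foot orientation),
#' which makes the inertial terms vanish identically and the consistency
#' exact up to resampling and filtering.
#'
#' Forces are sampled at 1,900 Hz and markers at 190 Hz. Vertical GRF
#' follows a smooth squared-sinusoid over the stance phase (60% of the
#' cycle) scaled to body weight; anteroposterior GRF a braking/propulsion
#' sinusoid. Stride-to-stride variation multiplies each cycle's torque
#' peak by `1 + torque_cv * z`.
#'
#' @param peak_torque_nm target peak plantarflexion torque (Nm, > 0).
#' @param stride_time_s stride duration (s, > 0).
#' @param belt_speed_ms treadmill belt speed (m/s).
#' @param n_strides number of strides (>= 1; the protocol uses >= 10).
#' @param body_mass_kg subject mass.
#' @param noise list: `grf_sd_n` iid noise on force channels (N),
#'   `marker_sd_m` on marker coordinates (m), `torque_cv` stride-to-stride
#'   SD of the torque peak as a fraction of the peak.
#' @param foot foot segment model: `mass_fraction` of body mass,
#'   `com_offset_m` ankle-to-COM vector in the foot frame,
#'   `gyration_m` radius of gyration about the COM.
#' @param seed integer seed.
#' @return object of class `gait_trial`: `force` (time_s, fx_n, fy_n,
#'   cop_x_m at 1,900 Hz), `markers` (time_s, ankle_x_m, ankle_y_m,
#'   foot_angle_rad at 190 Hz), `belt_speed_ms`, `body_mass_kg`, `foot`,
#'   and `truth` (per-cycle true peaks, stride time, stride count).
#' @export
generate_gait_trial <- function(peak_torque_nm,
                                stride_time_s = 1.11,
                                belt_speed_ms = 1.25,
                                n_strides = 12,
                                body_mass_kg = 75,
                                noise = list(grf_sd_n = 0, marker_sd_m = 0,
                                             torque_cv = 0),
                                foot = list(mass_fraction = 0.0145,
                                            com_offset_m = c(0.07, -0.03),
                                            gyration_m = 0.05),
                                seed = 1L) {
  if (peak_torque_nm <= 0) stop("peak_torque_nm must be > 0")
  if (stride_time_s <= 0) stop("stride_time_s must be > 0")
  if (n_strides < 1) stop("need at least one stride")
  fs_force <- 1900
  fs_marker <- 190
  stance_frac <- 0.6
  lead_s <- 0.2
  g <- 9.80665
  bw <- body_mass_kg * g
  m_f <- foot$mass_fraction * body_mass_kg

  dur <- lead_s + n_strides * stride_time_s + lead_s
  tf <- seq(0, dur, by = 1 / fs_force)
  tm <- seq(0, dur, by = 1 / fs_marker)

  ankle <- c(0.0, 0.08)
  foot_angle <- 0
  r_com <- ankle + foot$com_offset_m

  per_cycle_peak <- with_seed(child_seed(seed, 1L), {
    peak_torque_nm * (1 + noise$torque_cv * stats::rnorm(n_strides))
  })

  phase <- (tf - lead_s) / stride_time_s
  cyc <- floor(phase)
  in_gait <- phase >= 0 & cyc < n_strides
  ph <- phase - cyc                       # within-cycle phase 0..1
  phs <- ph / stance_frac                 # within-stance phase
  stance <- in_gait & ph < stance_frac

  fy <- ifelse(stance, 1.3 * bw * sin(pi * pmin(pmax(phs, 0), 1))^2, 0)
  fx <- ifelse(stance, -0.15 * bw * sin(2 * pi * pmin(pmax(phs, 0), 1)), 0)
  cyc_idx <- pmin(pmax(cyc, 0) + 1, n_strides)
  mt <- ifelse(in_gait,
               per_cycle_peak[cyc_idx] * exp(-((ph - 0.45) / 0.07)^2),
               0)
  mt[!stance] <- 0

  # back-compute COP from the target torque under the static foot model
  fa_x <- -fx
  fa_y <- m_f * g - fy
  c1 <- (ankle[1] - r_com[1]) * fa_y - (ankle[2] - r_com[2]) * fa_x
  cop <- rep(ankle[1], length(tf))
  on <- fy > 20
  cop[on] <- r_com[1] + (mt[on] - c1[on] - r_com[2] * fx[on]) / fy[on]
  cop <- pmin(pmax(cop, ankle[1] - 0.35), ankle[1] + 0.35)

  with_seed(child_seed(seed, 2L), {
    if (noise$grf_sd_n > 0) {
      fy <- fy + stats::rnorm(length(fy), 0, noise$grf_sd_n)
      fx <- fx + stats::rnorm(length(fx), 0, noise$grf_sd_n)
    }
    ank_x <- rep(ankle[1], length(tm))
    ank_y <- rep(ankle[2], length(tm))
    ang <- rep(foot_angle, length(tm))
    if (noise$marker_sd_m > 0) {
      ank_x <- ank_x + stats::rnorm(length(tm), 0, noise$marker_sd_m)
      ank_y <- ank_y + stats::rnorm(length(tm), 0, noise$marker_sd_m)
    }
    structure(list(force = data.frame(time_s = tf, fx_n = fx, fy_n = fy,
                                      cop_x_m = cop),
                   markers = data.frame(time_s = tm, ankle_x_m = ank_x,
                                        ankle_y_m = ank_y,
                                        foot_angle_rad = ang),
                   belt_speed_ms = belt_speed_ms,
                   body_mass_kg = body_mass_kg, foot = foot,
                   truth = list(peak_torque_nm = peak_torque_nm,
                                per_cycle_peak_nm = per_cycle_peak,
                                stride_time_s = stride_time_s,
                                stride_length_m = belt_speed_ms * stride_time_s,
                                n_strides = n_strides)),
              class = "gait_trial")
  })
}

#' Write a gait trial to a pair of TSV files
#'
#' `<prefix>_force.tsv` (1,900 Hz: time_s, fx_n, fy_n, cop_x_m) and
#' `<prefix>_markers.tsv` (190 Hz), plus `<prefix>_meta.json` (belt
#' speed, body mass, foot model). Column names carry the units.
#' @param trial a `gait_trial`.
#' @param prefix output path prefix.
#' @return paths, invisibly.
#' @export
write_gait_trial <- function(trial, prefix) {
  fp <- paste0(prefix, "_force.tsv")
  mp <- paste0(prefix, "_markers.tsv")
  jp <- paste0(prefix, "_meta.json")
  utils::write.table(trial$force, fp, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(trial$markers, mp, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(list(belt_speed_ms = trial$belt_speed_ms,
                            body_mass_kg = trial$body_mass_kg,
                            foot = trial$foot),
                       jp, auto_unbox = TRUE, digits = NA)
  invisible(c(fp, mp, jp))
}

#' Read a gait trial written by [write_gait_trial()]
#' @param prefix path prefix used when writing.
#' @return a `gait_trial` (without ground truth).
#' @export
read_gait_trial <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  structure(list(force = utils::read.delim(paste0(prefix, "_force.tsv")),
                 markers = utils::read.delim(paste0(prefix, "_markers.tsv")),
                 belt_speed_ms = meta$belt_speed_ms,
                 body_mass_kg = meta$body_mass_kg,
                 foot = as.list(meta$foot), truth = NULL),
            class = "gait_trial")
}
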