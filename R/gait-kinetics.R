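#' Detect heel-strike and toe-off events from vertical GRF
#'
#' Threshold crossing at `threshold_n` (default 20 N) with a debounce
#' window (default 50 ms): a crossing within the window of the previous
#' accepted event is ignored. Returned events strictly alternate
#' heel-strike / toe-off.
#'
#' @param vertical_grf_n vertical ground reaction force (N).
#' @param time_s sample times (s), same length.
#' @param threshold_n contact threshold (N).
#' @param debounce_s minimum time between accepted events (s).
#' @return list with `heel_strikes` and `toe_offs` (times in s).
#' @export
detect_gait_events <- function(vertical_grf_n, time_s, threshold_n = 20,
                               debounce_s = 0.05) {
  stopifnot(length(vertical_grf_n) == length(time_s))
  if (all(vertical_grf_n < threshold_n)) {
    stop("no force above the contact threshold; cannot detect events")
  }
  above <- vertical_grf_n >= threshold_n
  d <- diff(above)
  rises <- time_s[which(d == 1) + 1]
  falls <- time_s[which(d == -1) + 1]
  events <- rbind(data.frame(t = rises, type = "hs"),
                  data.frame(t = falls, type = "to"))
  events <- events[order(events$t), ]
  kept <- list()
  last_t <- -Inf
  last_type <- "to"   # a trial starts out of contact
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    if (e$t - last_t < debounce_s) next
    if (e$type == last_type) next
    kept[[length(kept) + 1]] <- e
    last_t <- e$t
    last_type <- e$type
  }
  kept <- do.call(rbind, kept)
  hs <- kept$t[kept$type == "hs"]
  if (length(hs) < 2) stop("fewer than 2 heel strikes detected")
  list(heel_strikes = hs, toe_offs = kept$t[kept$type == "to"])
}

#' Spatiotemporal gait parameters from events and belt speed
#'
#' Stride time is the mean interval between ipsilateral heel strikes; on
#' a treadmill, stride length is belt speed x stride time. Step length
#' defaults to half the stride (symmetric gait) and cadence to
#' 120 / stride time (steps/min).
#'
#' @param events result of [detect_gait_events()].
#' @param belt_speed_ms treadmill belt speed (m/s, > 0).
#' @return list: stride_time_s, stride_length_m, step_length_m,
#'   cadence_steps_min, n_strides, cv (coefficient of variation of the
#'   stride intervals).
#' @export
spatiotemporal <- function(events, belt_speed_ms) {
  if (belt_speed_ms <= 0) stop("belt speed must be > 0")
  hs <- events$heel_strikes
  if (length(hs) < 3) stop("need at least 3 ipsilateral heel strikes")
  iv <- diff(hs)
  cv <- stats::sd(iv) / mean(iv)
  if (is.finite(cv) && cv > 0.5) {
    warning("irregular gait events (stride-interval CV ", round(cv, 2),
            " > 0.5); parameters computed anyway")
  }
  st <- mean(iv)
  list(stride_time_s = st,
       stride_length_m = belt_speed_ms * st,
       step_length_m = belt_speed_ms * st / 2,
       cadence_steps_min = 120 / st,
       n_strides = length(iv), cv = cv)
}

# Zero-lag low-pass: 2nd-order Butterworth applied forward and backward
# (4th-order effective response).
lowpass <- function(x, fs, cutoff_hz) {
  if (is.null(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= fs / 2) return(x)
  bf <- signal::butter(2, cutoff_hz / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

#' Sagittal-plane ankle inverse dynamics over gait cycles
#'
#' Newton-Euler on the foot segment in the sagittal plane (x anterior,
#' y vertical): the net ankle moment balances the ground reaction force
#' applied at the center of pressure, the foot's weight, and the foot's
#' inertial terms (mass x acceleration at the COM, I * alpha). Reported
#' plantarflexion-positive: a vertical GRF applied anterior to the ankle
#' yields a positive (plantarflexion) moment. Force channels are low-pass
#' filtered at `force_cutoff_hz`, kinematics at `marker_cutoff_hz`
#' (zero-lag), forces are interpolated onto the kinematic time base, the
#' per-cycle moment waveform is time-normalized to 101 points from heel
#' strike to ipsilateral heel strike, and the per-cycle peaks are
#' averaged.
#'
#' @param trial a `gait_trial`.
#' @param force_cutoff_hz low-pass cutoff for force channels (Hz).
#' @param marker_cutoff_hz low-pass cutoff for kinematics (Hz).
#' @return object of class `joint_kinetics`: `cycles` (101 x n matrix of
#'   per-cycle moment waveforms, Nm), `peak_per_cycle_nm`,
#'   `mean_peak_nm`, `sd_peak_nm`, `spatiotemporal`, `events`.
#' @export
ankle_inverse_dynamics <- function(trial, force_cutoff_hz = 25,
                                   marker_cutoff_hz = 6) {
  f <- trial$force
  m <- trial$markers
  foot <- trial$foot
  if (is.null(foot) || is.null(foot$mass_fraction)) {
    warning("missing foot anthropometrics; applying defaults ",
            "(mass fraction 0.0145 of body mass)")
    foot <- list(mass_fraction = 0.0145, com_offset_m = c(0.07, -0.03),
                 gyration_m = 0.05)
  }
  g <- 9.80665
  m_f <- foot$mass_fraction * trial$body_mass_kg

  fs_f <- 1 / stats::median(diff(f$time_s))
  fs_m <- 1 / stats::median(diff(m$time_s))
  fx <- lowpass(f$fx_n, fs_f, force_cutoff_hz)
  fy <- lowpass(f$fy_n, fs_f, force_cutoff_hz)

  # detect contact on the filtered channel so sensor noise cannot fire
  # spurious crossings
  events <- detect_gait_events(fy, f$time_s)
  ank_x <- lowpass(m$ankle_x_m, fs_m, marker_cutoff_hz)
  ank_y <- lowpass(m$ankle_y_m, fs_m, marker_cutoff_hz)
  ang <- lowpass(m$foot_angle_rad, fs_m, marker_cutoff_hz)

  tmk <- m$time_s
  fx_k <- stats::approx(f$time_s, fx, xout = tmk, rule = 2)$y
  fy_k <- stats::approx(f$time_s, fy, xout = tmk, rule = 2)$y
  cop_k <- stats::approx(f$time_s, f$cop_x_m, xout = tmk, rule = 2)$y

  # foot COM kinematics
  off <- foot$com_offset_m
  com_x <- ank_x + cos(ang) * off[1] - sin(ang) * off[2]
  com_y <- ank_y + sin(ang) * off[1] + cos(ang) * off[2]
  dt <- 1 / fs_m
  accel <- function(x) {
    n <- length(x)
    a <- c(0, (x[-(1:2)] - 2 * x[-c(1, n)] + x[-((n - 1):n)]) / dt^2, 0)
    a
  }
  ax <- accel(com_x)
  ay <- accel(com_y)
  alpha <- accel(ang)
  inertia <- m_f * foot$gyration_m^2

  # ankle joint reaction force on the foot
  fa_x <- m_f * ax - fx_k
  fa_y <- m_f * ay + m_f * g - fy_k
  cross2 <- function(ux, uy, vx, vy) ux * vy - uy * vx
  m_ank <- inertia * alpha -
    cross2(ank_x - com_x, ank_y - com_y, fa_x, fa_y) -
    cross2(cop_k - com_x, 0 - com_y, fx_k, fy_k)
  m_pf <- -m_ank

  hs <- events$heel_strikes
  n_cyc <- length(hs) - 1
  cycles <- matrix(NA_real_, 101, n_cyc)
  for (c in seq_len(n_cyc)) {
    tq <- seq(hs[c], hs[c + 1], length.out = 101)
    cycles[, c] <- stats::approx(tmk, m_pf, xout = tq, rule = 2)$y
  }
  peaks <- apply(cycles, 2, max)
  structure(list(cycles = cycles, peak_per_cycle_nm = peaks,
                 mean_peak_nm = mean(peaks), sd_peak_nm = stats::sd(peaks),
                 spatiotemporal = spatiotemporal(events, trial$belt_speed_ms),
                 events = events),
            class = "joint_kinetics")
}

#' @export
print.joint_kinetics <- function(x, ...) {
  cat("joint_kinetics: ", length(x$peak_per_cycle_nm), " cycles, mean peak ",
      round(x$mean_peak_nm, 1), " +/- ", round(x$sd_peak_nm, 1), " Nm\n",
      sep = "")
  invisible(x)
}

#' Estimate peak Achilles tendon force from torque and moment arm
#'
#' Assumes the plantarflexion torque is generated entirely by the triceps
#' surae acting through the Achilles tendon: force = torque / moment arm
#' (moment arm converted from mm to m).
#'
#' @param mean_peak_torque_nm mean peak plantarflexion torque (Nm).
#' @param moment_arm_mm Achilles tendon moment arm (mm, > 0).
#' @return tendon force in N.
#' @export
estimate_tendon_force <- function(mean_peak_torque_nm, moment_arm_mm) {
  if (moment_arm_mm <= 0) stop("moment arm must be > 0")
  mean_peak_torque_nm / (moment_arm_mm / 1000)
}
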