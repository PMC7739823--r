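# Shared fixtures and independent oracles used across the test files.

# A noise-free zero-scatter cohort configuration: every generated value
# lies exactly on its generating line.
zero_noise_config <- function(seed = 1L, n_young = 6, n_older = 4) {
  cohort_config(
    n_young = n_young, n_older = n_older,
    height_dist = list(young = c(1.75, 0.08), older = c(1.76, 0.07)),
    mass_dist = list(young = c(80, 10), older = c(74.57, 12)),
    volume_noise_sd = c(young = 0, older = 0),
    fraction_noise_sd = 0,
    tendon_coupling = list(
      young = list(coupled = TRUE, slope = 0.05, intercept = 16.56,
                   resid_sd = 0),
      older = list(coupled = FALSE, mean = 65.54, sd = 0.5)),
    moment_arm_mean_sd = list(young = c(46.64, 0), older = c(43.54, 0)),
    torque_resid_sd = c(young = 0, older = 0),
    seed = seed)
}

# Hinge poses about a known axis (point p0, unit direction d), angles in
# degrees; exact rigid poses with the axis as the fixed line.
hinge_poses <- function(p0, d, angles_deg) {
  lapply(angles_deg, function(a) {
    R <- tsmorph:::rotation_about_axis(d, a)
    structure(list(R = R, t = as.numeric(p0 - R %*% p0), rms = 0),
              class = "rigid_pose")
  })
}

# Independent skew-line distance oracle: minimize ||a(s) - b(t)|| over
# the two line parameters as a numerical least-squares problem (QR),
# ||(p1 - p2) + [d1, -d2] (s, t)'||, independent of the implementation's
# cross-product formula.
skew_distance_oracle <- function(p1, d1, p2, d2) {
  X <- cbind(d1, -d2)
  v <- p1 - p2
  st <- qr.coef(qr(X), -v)
  st[is.na(st)] <- 0
  sqrt(sum((v + X %*% st)^2))
}

# Brute-force exact Mann-Whitney oracle: enumerate every assignment of
# the pooled values to group a, tally the U statistic, and double the
# smaller tail. Assumes no ties.
mann_whitney_bruteforce <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(length(pooled), na)
  us <- apply(combos, 2, function(idx) {
    sum(rank(pooled)[idx]) - na * (na + 1) / 2
  })
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Hand step-down Holm oracle, written as the literal definition.
holm_oracle <- function(p, cap = FALSE) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    val <- (m - i + 1) * p[o[i]]
    running <- max(running, val)
    adj[o[i]] <- running
  }
  if (cap) adj <- pmin(adj, 1)
  adj
}

# A minimal hand-built gait trial: square-wave vertical GRF at a fixed
# COP offset, stationary foot.
square_wave_trial <- function(fy_contact, cop_offset_m, n_cycles = 3,
                              stride_s = 1.0, stance_frac = 0.5,
                              mass_fraction = 0, body_mass = 75) {
  fs <- 1900
  t <- seq(0, n_cycles * stride_s + 0.2, by = 1 / fs)
  ph <- (t - 0.1) / stride_s
  stance <- ph >= 0 & ph < n_cycles & (ph - floor(ph)) < stance_frac
  ankle <- c(0, 0.08)
  tm <- seq(0, max(t), by = 1 / 190)
  structure(list(
    force = data.frame(time_s = t, fx_n = 0,
                       fy_n = ifelse(stance, fy_contact, 0),
                       cop_x_m = ankle[1] + cop_offset_m),
    markers = data.frame(time_s = tm, ankle_x_m = ankle[1],
                         ankle_y_m = ankle[2], foot_angle_rad = 0),
    belt_speed_ms = 1.25, body_mass_kg = body_mass,
    foot = list(mass_fraction = mass_fraction,
                com_offset_m = c(0.07, -0.03), gyration_m = 0.05),
    truth = NULL), class = "gait_trial")
}

# Rasterize a freely-oriented ellipsoid by the center-inside rule
# (independent of the package's axis-aligned rasterizer).
rasterize_rotated_ellipsoid <- function(semi, R, spacing, pad = 4) {
  ext <- sqrt(rowSums((R %*% diag(semi))^2)) + pad
  nx <- ceiling(2 * ext / spacing)
  ctr <- (nx - 1) * spacing / 2
  xs <- lapply(1:3, function(a) (seq_len(nx[a]) - 1) * spacing[a] - ctr[a])
  arr <- array(0L, nx)
  Rt <- t(R)
  for (k in seq_len(nx[3])) {
    g <- expand.grid(x = xs[[1]], y = xs[[2]])
    pts <- cbind(g$x, g$y, xs[[3]][k]) %*% t(Rt)
    inside <- rowSums(sweep(pts, 2, semi, "/")^2) <= 1
    arr[, , k] <- matrix(as.integer(inside), nx[1], nx[2])
  }
  arr
}
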