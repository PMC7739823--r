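test_that("gait events fall exactly on threshold crossings of a square wave", {
  fs <- 1900
  t <- seq(0, 3, by = 1 / fs)
  fy <- ifelse((t %% 1) >= 0.1 & (t %% 1) < 0.7, 800, 0)
  ev <- detect_gait_events(fy, t)
  expect_equal(length(ev$heel_strikes), 3)
  expect_lt(max(abs(ev$heel_strikes - c(0.1, 1.1, 2.1))), 1.5 / fs)
  expect_lt(max(abs(ev$toe_offs - c(0.7, 1.7, 2.7))), 1.5 / fs)
  expect_error(detect_gait_events(rep(0, 100), seq(0, 1, length.out = 100)),
               "threshold")
})

test_that("chatter near the threshold is debounced", {
  fs <- 1900
  t <- seq(0, 2.5, by = 1 / fs)
  fy <- ifelse((t %% 1) >= 0.1 & (t %% 1) < 0.7, 800, 0)
  # inject a 5 ms dropout inside stance
  fy[t > 1.3 & t < 1.305] <- 0
  ev <- detect_gait_events(fy, t)
  expect_equal(length(ev$heel_strikes), 3)
})

test_that("spatiotemporal parameters follow the defining arithmetic", {
  ev <- list(heel_strikes = c(0, 1.11, 2.22), toe_offs = c(0.7, 1.81))
  st <- spatiotemporal(ev, 1.25)
  expect_equal(st$stride_time_s, 1.11)
  expect_equal(st$stride_length_m, 1.3875)
  expect_equal(st$step_length_m, 1.3875 / 2)
  expect_equal(st$cadence_steps_min, 120 / 1.11)  # ~108.1 steps/min
  st2 <- spatiotemporal(list(heel_strikes = c(0, 1.02, 2.04)), 1.25)
  expect_equal(st2$cadence_steps_min, 120 / 1.02)  # ~117.6
  expect_error(spatiotemporal(list(heel_strikes = c(0, 1)), 1.25),
               "3 ipsilateral")
  expect_warning(spatiotemporal(list(heel_strikes = c(0, 0.4, 2.1, 2.5)),
                                1.25), "irregular")
})

test_that("static loading reduces to force times lever arm", {
  # 735.75 N body weight at a COP 0.12 m anterior to the ankle with a
  # massless foot: plantarflexion moment 88.29 Nm, exact
  trial <- square_wave_trial(735.75, 0.12)
  jk <- ankle_inverse_dynamics(trial, force_cutoff_hz = 0,
                               marker_cutoff_hz = 0)
  expect_equal(jk$mean_peak_nm, 735.75 * 0.12, tolerance = 1e-9)

  # doubling GRF doubles the massless-foot moment exactly
  trial2 <- square_wave_trial(2 * 735.75, 0.12)
  jk2 <- ankle_inverse_dynamics(trial2, force_cutoff_hz = 0,
                                marker_cutoff_hz = 0)
  expect_equal(jk2$mean_peak_nm, 2 * jk$mean_peak_nm, tolerance = 1e-9)

  # zero GRF with a stationary massless foot: zero moment everywhere
  trial3 <- square_wave_trial(735.75, 0)
  jk3 <- ankle_inverse_dynamics(trial3, force_cutoff_hz = 0,
                                marker_cutoff_hz = 0)
  expect_equal(jk3$mean_peak_nm, 0, tolerance = 1e-9)
})

test_that("inverse dynamics closes the loop on generated trials", {
  g <- generate_gait_trial(114, n_strides = 10,
                           noise = list(grf_sd_n = 0, marker_sd_m = 0,
                                        torque_cv = 0))
  jk <- ankle_inverse_dynamics(g)
  expect_equal(length(jk$peak_per_cycle_nm) + 1,
               length(jk$events$heel_strikes))
  expect_lt(abs(jk$mean_peak_nm - 114) / 114, 0.01)
  expect_equal(jk$spatiotemporal$stride_time_s, 1.11, tolerance = 2e-3)
  expect_equal(jk$spatiotemporal$stride_length_m, 1.3875, tolerance = 3e-3)

  g2 <- generate_gait_trial(114, n_strides = 12, seed = 4,
                            noise = list(grf_sd_n = 5, marker_sd_m = 5e-4,
                                         torque_cv = 0.05))
  jk2 <- ankle_inverse_dynamics(g2)
  true_mean <- mean(g2$truth$per_cycle_peak_nm)
  expect_lt(abs(jk2$mean_peak_nm - true_mean) / true_mean, 0.05)
})

test_that("detected stride count equals the generated count", {
  for (n in c(10, 14)) {
    g <- generate_gait_trial(100, n_strides = n,
                             noise = list(grf_sd_n = 0, marker_sd_m = 0,
                                          torque_cv = 0))
    ev <- detect_gait_events(g$force$fy_n, g$force$time_s)
    expect_equal(length(ev$heel_strikes), n)
  }
})

test_that("the moment waveform is invariant to uniform time shifts", {
  g <- generate_gait_trial(110, n_strides = 10,
                           noise = list(grf_sd_n = 0, marker_sd_m = 0,
                                        torque_cv = 0))
  g2 <- g
  g2$force$time_s <- g2$force$time_s + 0.37
  g2$markers$time_s <- g2$markers$time_s + 0.37
  jk <- ankle_inverse_dynamics(g)
  jk2 <- ankle_inverse_dynamics(g2)
  expect_equal(jk2$mean_peak_nm, jk$mean_peak_nm, tolerance = 1e-9)
  expect_equal(jk2$cycles, jk$cycles, tolerance = 1e-9)
})

test_that("generator rejects degenerate requests", {
  expect_error(generate_gait_trial(0), "peak_torque_nm")
  expect_error(generate_gait_trial(-5), "peak_torque_nm")
  expect_error(generate_gait_trial(100, stride_time_s = 0), "stride_time_s")
  expect_error(generate_gait_trial(100, n_strides = 0), "at least one stride")
})

test_that("ground-truth stride length is belt speed times stride time", {
  g <- generate_gait_trial(100, stride_time_s = 1.11, belt_speed_ms = 1.25,
                           n_strides = 10,
                           noise = list(grf_sd_n = 0, marker_sd_m = 0,
                                        torque_cv = 0))
  expect_equal(g$truth$stride_length_m, 1.3875)
})

test_that("missing foot anthropometrics fall back to defaults with a warning", {
  g <- generate_gait_trial(100, n_strides = 10,
                           noise = list(grf_sd_n = 0, marker_sd_m = 0,
                                        torque_cv = 0))
  g$foot <- NULL
  expect_warning(jk <- ankle_inverse_dynamics(g), "mass fraction 0.0145")
  expect_lt(abs(jk$mean_peak_nm - 100) / 100, 0.01)
})

test_that("tendon force estimation is torque over moment arm in meters", {
  expect_equal(estimate_tendon_force(100, 50), 2000)
  expect_equal(estimate_tendon_force(114.23, 46.64), 114.23 / 0.04664)
  expect_equal(estimate_tendon_force(114.23, 46.64), 2449.2, tolerance = 1e-4)
  expect_equal(estimate_tendon_force(0, 46), 0)
  expect_error(estimate_tendon_force(100, 0), "> 0")
})

test_that("gait trials round-trip through TSV files", {
  dir <- withr::local_tempdir()
  g <- generate_gait_trial(105, n_strides = 10, seed = 2,
                           noise = list(grf_sd_n = 2, marker_sd_m = 1e-4,
                                        torque_cv = 0.05))
  write_gait_trial(g, file.path(dir, "walk"))
  back <- read_gait_trial(file.path(dir, "walk"))
  jk_a <- ankle_inverse_dynamics(g)
  jk_b <- ankle_inverse_dynamics(back)
  expect_equal(jk_b$mean_peak_nm, jk_a$mean_peak_nm, tolerance = 1e-6)
})
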