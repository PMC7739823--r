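ref_markers <- rbind(c(0, 0, 0), c(100, 0, 0), c(0, 80, 0), c(30, 20, 60))

test_that("rigid pose recovery is exact for noiseless constructions", {
  p0 <- fit_rigid_pose(ref_markers, ref_markers)
  expect_equal(p0$R, diag(3), tolerance = 1e-12)
  expect_equal(p0$t, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(p0$rms, 0, tolerance = 1e-12)

  R30 <- tsmorph:::rotation_about_axis(c(0, 0, 1), 30)
  obs <- ref_markers %*% t(R30) + matrix(c(5, -3, 12), 4, 3, byrow = TRUE)
  p <- fit_rigid_pose(ref_markers, obs)
  expect_equal(tsmorph:::rotation_axis_angle(p$R)$angle_deg, 30,
               tolerance = 1e-9)
  expect_equal(p$t, c(5, -3, 12), tolerance = 1e-9)
  expect_equal(det(p$R), 1, tolerance = 1e-12)
  expect_equal(t(p$R) %*% p$R, diag(3), tolerance = 1e-9)
})

test_that("pose residual RMS is consistent with marker noise", {
  set.seed(42)
  rms <- replicate(100, {
    obs <- ref_markers + matrix(rnorm(12, 0, 0.5), 4, 3)
    fit_rigid_pose(ref_markers, obs)$rms
  })
  # residual absorbs 6 pose dof from 12 coordinates: E[rms^2] ~ sd^2/2
  expect_equal(mean(rms^2), 0.25 * 0.5, tolerance = 0.25)
})

test_that("degenerate marker sets are rejected", {
  line <- cbind(seq(0, 30, 10), 0, 0)
  expect_error(fit_rigid_pose(line, line), "collinear")
  expect_error(fit_rigid_pose(ref_markers, ref_markers[1:3, ]),
               "matching dimensions")
  expect_error(fit_rigid_pose(ref_markers[1:2, ], ref_markers[1:2, ]),
               "3 markers")
})

test_that("functional axis recovery on a pure hinge is near-exact", {
  d <- tsmorph:::unitize(c(0.9, 0.3, 0.2))
  p0 <- c(10, -20, 35)
  poses <- hinge_poses(p0, d, seq(-18, 18, by = 1.5))
  ax <- fit_functional_axis(poses)
  expect_lt(acos(min(1, abs(sum(ax$direction * d)))) * 180 / pi, 0.01)
  v <- ax$point - p0
  off_axis <- v - sum(v * d) * d
  expect_lt(tsmorph:::vnorm(off_axis), 0.01)
})

test_that("insufficient rotation is rejected", {
  poses <- hinge_poses(c(0, 0, 0), c(1, 0, 0), rep(0, 12))
  expect_error(fit_functional_axis(poses), "insufficient range of motion")
  poses2 <- hinge_poses(c(0, 0, 0), c(1, 0, 0), seq(0, 3, by = 0.3))
  expect_error(fit_functional_axis(poses2), "insufficient range of motion")
})

test_that("axis direction stays within 1 degree under marker noise", {
  d <- tsmorph:::unitize(c(0.97, 0.17, 0.17))
  p0 <- c(30, 40, 60)
  hits <- 0
  for (s in 1:100) {
    set.seed(s)
    poses <- lapply(seq(-15, 15, by = 1), function(a) {
      R <- tsmorph:::rotation_about_axis(d, a)
      tpose <- as.numeric(p0 - R %*% p0)
      obs <- ref_markers %*% t(R) +
        matrix(tpose, 4, 3, byrow = TRUE) + matrix(rnorm(12, 0, 0.5), 4, 3)
      fit_rigid_pose(ref_markers, obs)
    })
    ax <- fit_functional_axis(poses)
    err <- acos(min(1, abs(sum(ax$direction * d)))) * 180 / pi
    if (err < 1) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("tendon line fit is exact for symmetric edges and equivariant", {
  dir <- tsmorph:::unitize(c(0.1, 0.2, 1))
  pt <- c(5, 40, 10)
  centers <- matrix(pt, 8, 3, byrow = TRUE) +
    outer(seq(-20, 20, length.out = 8), dir)
  off <- tsmorph:::unitize(tsmorph:::cross3(dir, c(1, 0, 0)))
  line <- fit_tendon_line(centers + 2.5 * matrix(off, 8, 3, byrow = TRUE),
                          centers - 2.5 * matrix(off, 8, 3, byrow = TRUE))
  expect_lt(acos(min(1, abs(sum(line$direction * dir)))) * 180 / pi, 1e-9)
  resid <- line$point - pt
  expect_lt(tsmorph:::vnorm(resid - sum(resid * dir) * dir), 1e-9)

  # a known rigid pose applied to the edge points transforms the line the
  # same way: express points in a probe frame and map them back out
  Rp <- tsmorph:::rotation_about_axis(c(1, 1, 0), 25)
  probe <- structure(list(R = Rp, t = c(10, -5, 30), rms = 0),
                     class = "rigid_pose")
  to_probe <- function(m) tsmorph:::pose_apply(tsmorph:::pose_invert(probe), m)
  line2 <- fit_tendon_line(to_probe(centers + 2.5 * matrix(off, 8, 3, byrow = TRUE)),
                           to_probe(centers - 2.5 * matrix(off, 8, 3, byrow = TRUE)),
                           probe_pose = probe, shank_pose = NULL)
  expect_lt(acos(min(1, abs(sum(line2$direction * dir)))) * 180 / pi, 1e-9)
  expect_error(fit_tendon_line(centers[1:1, , drop = FALSE],
                               centers[1:1, , drop = FALSE]), "at least 2")
  same <- matrix(pt, 4, 3, byrow = TRUE)
  expect_error(fit_tendon_line(same, same), "coincide")
})

test_that("skew-line moment arm matches constructed and degenerate cases", {
  axis <- list(direction = c(1, 0, 0), point = c(0, 0, 0))
  line <- list(direction = c(0, 0, 1), point = c(0, 46.64, 0))
  expect_equal(compute_moment_arm(line, axis), 46.64)
  expect_equal(compute_moment_arm(axis, line), 46.64)  # symmetry
  crossing <- list(direction = c(0, 1, 1), point = c(0, 0, 0))
  expect_equal(compute_moment_arm(crossing, axis), 0)
  parallel <- list(direction = c(1, 0, 0), point = c(5, 3, 4))
  expect_equal(compute_moment_arm(parallel, axis), 5)
})

test_that("skew-line distance agrees with a numerical-minimization oracle", {
  set.seed(7)
  for (i in 1:200) {
    p1 <- rnorm(3, 0, 50); d1 <- tsmorph:::unitize(rnorm(3))
    p2 <- rnorm(3, 0, 50); d2 <- tsmorph:::unitize(rnorm(3))
    got <- compute_moment_arm(list(direction = d1, point = p1),
                              list(direction = d2, point = p2))
    expect_equal(got, skew_distance_oracle(p1, d1, p2, d2),
                 tolerance = 1e-6)
  }
})

test_that("moment arm is invariant under a common rigid transform", {
  set.seed(3)
  R <- tsmorph:::rotation_about_axis(c(2, -1, 0.5), 73)
  tt <- c(15, -40, 22)
  for (i in 1:20) {
    p1 <- rnorm(3, 0, 30); d1 <- tsmorph:::unitize(rnorm(3))
    p2 <- rnorm(3, 0, 30); d2 <- tsmorph:::unitize(rnorm(3))
    a <- compute_moment_arm(list(direction = d1, point = p1),
                            list(direction = d2, point = p2))
    b <- compute_moment_arm(
      list(direction = as.numeric(R %*% d1), point = as.numeric(R %*% p1 + tt)),
      list(direction = as.numeric(R %*% d2), point = as.numeric(R %*% p2 + tt)))
    expect_equal(a, b, tolerance = 1e-9)
  }
})

test_that("quadratic neutral fit recovers exact polynomials", {
  a <- seq(-20, 20, by = 1)
  ma <- 46 - 0.1 * a - 0.01 * a^2
  cur <- moment_arm_at_neutral(a, ma)
  expect_equal(unname(cur$coefficients), c(46, -0.1, -0.01), tolerance = 1e-9)
  expect_equal(cur$moment_arm_0deg_mm, 46, tolerance = 1e-9)

  flat <- moment_arm_at_neutral(a, rep(40, length(a)))
  expect_equal(unname(flat$coefficients), c(40, 0, 0), tolerance = 1e-9)

  expect_error(moment_arm_at_neutral(a[1:4], ma[1:4]), "5 frames")
  expect_error(moment_arm_at_neutral(rep(c(-5, 5), 5), rep(40, 10)),
               "3 distinct")
  expect_error(moment_arm_at_neutral(seq(10, 30), rep(40, 21)), "bracket")
})

test_that("neutral estimate is nearly unbiased under measurement noise", {
  a <- seq(-15, 15, length.out = 50)
  truth <- 46 - 0.1 * a - 0.01 * a^2
  set.seed(11)
  c0 <- replicate(200, {
    moment_arm_at_neutral(a, truth + rnorm(50, 0, 0.5))$moment_arm_0deg_mm
  })
  expect_lt(abs(mean(c0) - 46), 0.2)
})

test_that("noiseless synthetic trials reproduce the generator's curve", {
  axis_dir <- tsmorph:::unitize(c(0.97, 0.17, 0.17))
  rom <- generate_rom_trial(axis = list(point = c(30, 40, 60),
                                        direction = axis_dir),
                            quad_coeffs = c(46, -0.1, -0.01),
                            marker_noise_sd = 0)
  res <- analyze_rom_trial(rom)
  expect_lt(acos(min(1, abs(sum(res$axis$direction * axis_dir)))) * 180 / pi,
            0.1)
  expect_lt(abs(res$moment_arm_0deg_mm - 46), 0.1)
  expect_equal(unname(res$curve$coefficients), c(46, -0.1, -0.01),
               tolerance = 1e-6)
})

test_that("ROM trials round-trip through TSV and reanalyze identically", {
  dir <- withr::local_tempdir()
  rom <- generate_rom_trial(axis = list(point = c(30, 40, 60),
                                        direction = c(0.97, 0.17, 0.17)),
                            marker_noise_sd = 0.3, seed = 5)
  write_rom_trial(rom, file.path(dir, "trial"))
  back <- read_rom_trial(file.path(dir, "trial"))
  a <- analyze_rom_trial(rom)
  b <- analyze_rom_trial(back)
  expect_equal(b$moment_arm_0deg_mm, a$moment_arm_0deg_mm, tolerance = 1e-9)
})

test_that("degenerate ROM inputs are rejected", {
  expect_error(generate_rom_trial(axis = list(point = c(0, 0, 0),
                                              direction = c(0, 0, 0))),
               "degenerate axis")
  expect_error(generate_rom_trial(axis = list(point = c(0, 0, 0),
                                              direction = c(1, 0, 0)),
                                  angles_deg = seq(-5, 5)),
               "cover at least")
})
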