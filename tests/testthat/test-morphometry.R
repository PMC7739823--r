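make_block_volume <- function(spacing = c(0.72, 0.72, 2)) {
  # one big PS block plus single voxels of the other muscles
  arr <- array(0L, c(104, 104, 52))
  arr[1:100, 1:100, 1:50] <- 1L
  arr[102, 102, 51] <- 2L
  arr[103, 102, 51] <- 3L
  arr[104, 102, 51] <- 4L
  label_volume(arr, spacing)
}

test_that("muscle volume is voxel count times voxel volume", {
  vol <- make_block_volume()
  mm <- compute_muscle_volumes(vol, 1.75, 80)
  expect_equal(mm$volumes_cm3[["PS"]],
               100 * 100 * 50 * 0.72 * 0.72 * 2 / 1000)  # 518.4 cm^3
  expect_equal(mm$total_cm3, sum(mm$volumes_cm3))
  expect_equal(sum(mm$relative_pct), 100, tolerance = 1e-9)
})

test_that("relative and normalized volumes follow the defining arithmetic", {
  # exact volumes (400, 80, 300, 170) cm^3 from integer voxel counts
  arr <- array(0L, c(100, 100, 10))
  arr[, , 1:2] <- 1L                     # 20000 voxels
  arr[1:40, , 3] <- 2L                   # 4000
  arr[, , 4] <- 3L
  arr[1:50, , 5] <- 3L                   # 15000
  arr[51:100, , 5] <- 4L
  arr[1:35, , 6] <- 4L                   # 5000 + 3500 = 8500
  vol <- label_volume(arr, c(2, 2, 5))   # 20 mm^3 voxels
  mm <- compute_muscle_volumes(vol, 1.75, 80)
  expect_equal(unname(mm$volumes_cm3), c(400, 80, 300, 170))
  expect_equal(mm$total_cm3, 950)
  expect_equal(mm$relative_pct[["PS"]], 400 / 950 * 100)  # 42.105...%
  expect_equal(unname(mm$normalized_cm3_per_kgm["total"]), 950 / 140)
  # a 700 cm^3 volume at 1.75 m, 80 kg normalizes to exactly 5 cm^3/(kg*m)
  vec <- integer(100 * 100 * 38)
  vec[1:35000] <- 1L                      # 35000 x 20 mm^3 = 700 cm^3
  vec[35001:36000] <- 2L
  vec[36001:37000] <- 3L
  vec[37001:38000] <- 4L
  mm700 <- compute_muscle_volumes(
    label_volume(array(vec, c(100, 100, 38)), c(2, 2, 5)), 1.75, 80)
  expect_equal(unname(mm700$normalized_cm3_per_kgm["PS"]),
               35000 * 20 / 1000 / 140)  # 700 cm^3 -> 5.00
  expect_equal(unname(mm700$normalized_cm3_per_kgm["PS"]), 5)
})

test_that("missing labels and empty volumes raise informative errors", {
  arr <- array(0L, c(4, 4, 4))
  arr[1, 1, 1] <- 1L
  arr[2, 1, 1] <- 2L
  arr[3, 1, 1] <- 3L
  vol <- label_volume(arr, c(1, 1, 1))
  expect_error(compute_muscle_volumes(vol), "LG")
})

test_that("volume is additive under label splitting", {
  v <- generate_label_volume(c(PS = 90, AS = 25, MG = 70, LG = 40))
  mm <- compute_muscle_volumes(v, 1.7, 70)
  # split PS voxels into two halves and sum them back
  idx <- which(v$data == 1L)
  half <- idx[seq_len(floor(length(idx) / 2))]
  arr2 <- v$data
  arr2[half] <- 2L   # merge into AS: (PS + AS) must keep the same total
  v2 <- label_volume(arr2, v$spacing)
  mm2 <- compute_muscle_volumes(v2, 1.7, 70)
  expect_equal(mm2$volumes_cm3[["PS"]] + mm2$volumes_cm3[["AS"]],
               mm$volumes_cm3[["PS"]] + mm$volumes_cm3[["AS"]])
  expect_equal(mm2$total_cm3, mm$total_cm3)
})

test_that("relative volumes are invariant to uniform spacing rescaling", {
  v <- generate_label_volume(c(PS = 90, AS = 25, MG = 70, LG = 40))
  mm1 <- compute_muscle_volumes(v, 1.7, 70)
  v2 <- label_volume(v$data, v$spacing * 3)
  mm2 <- compute_muscle_volumes(v2, 1.7, 70)
  expect_equal(mm1$relative_pct, mm2$relative_pct)
})

test_that("rigid rotation changes measured volume only by resampling error", {
  semi <- c(24, 17, 55)
  spacing <- c(0.72, 0.72, 2)
  analytic <- 4 / 3 * pi * prod(semi) / 1000
  for (ang in c(0, 30)) {
    R <- tsmorph:::rotation_about_axis(c(0, 0, 1), ang)
    arr <- rasterize_rotated_ellipsoid(semi, R, spacing)
    measured <- sum(arr) * prod(spacing) / 1000
    expect_lt(abs(measured - analytic) / analytic, 0.015)
  }
})

test_that("tendon geometry recovers the straight cylinder", {
  v <- generate_label_volume(tendon = tendon_spec(pi * 16, 26))
  tg <- tendon_geometry(v)
  expect_equal(tg$length_mm, 50, tolerance = 1e-9)   # collinear centroids
  expect_lt(abs(tg$mid_csa_mm2 - pi * 16) / (pi * 16), 0.03)
  expect_lt(abs(tg$volume_cm3 - 26 * pi * 16 * 2 / 1000) /
              (26 * pi * 16 * 2 / 1000), 0.03)
  expect_equal(nrow(tg$profile), 101)
  expect_equal(range(tg$profile$length_pct), c(0, 100))
})

test_that("an inclined tube's path length is the axial extent over cos(angle)", {
  v <- generate_label_volume(tendon = tendon_spec(pi * 16, 26,
                                                  incline_deg = 30))
  tg <- tendon_geometry(v)
  expect_lt(abs(tg$length_mm - 50 / cos(30 * pi / 180)) /
              (50 / cos(30 * pi / 180)), 0.02)
})

test_that("a single-slice tendon degenerates cleanly", {
  v <- generate_label_volume(tendon = tendon_spec(60, 1))
  tg <- tendon_geometry(v)
  expect_equal(tg$length_mm, 0)
  expect_equal(tg$volume_cm3, tg$csa_mm2[1] * 2 / 1000)
  expect_equal(tg$mid_csa_mm2, tg$csa_mm2[1])
})

test_that("a gap in the tendon label is reported with slice indices", {
  v <- generate_label_volume(tendon = tendon_spec(50, 12))
  k_gap <- v$truth$tendon$slices[6]
  arr <- v$data
  sl <- arr[, , k_gap]
  sl[sl == 5L] <- 0L
  arr[, , k_gap] <- sl
  v2 <- label_volume(arr, v$spacing)
  expect_error(tendon_geometry(v2), as.character(k_gap))
})

test_that("landmarks can come from a sidecar instead of labels", {
  v <- generate_label_volume(tendon = tendon_spec(50, 12))
  tg_lab <- tendon_geometry(v)
  tg_side <- tendon_geometry(v, landmarks = list(
    calcaneus_top = v$truth$tendon$slices[1],
    soleus_mtj = v$truth$tendon$slices[12]))
  expect_equal(tg_side$csa_mm2, tg_lab$csa_mm2)
  expect_equal(tg_side$length_mm, tg_lab$length_mm)
})

test_that("tendon/muscle ratios are unit-consistent", {
  morpho <- structure(list(
    volumes_cm3 = c(PS = 394.9, AS = 83.2, MG = 288.7, LG = 175.1),
    total_cm3 = 941.9,
    relative_pct = c(PS = 0, AS = 0, MG = 0, LG = 0),
    normalized_cm3_per_kgm = NA, height_mass_kgm = 120),
    class = "muscle_morphometry")
  r <- tendon_muscle_ratios(61.35, morpho)
  expect_equal(unname(r$csa_per_volume_cm["total"]), 0.6135 / 941.9,
               tolerance = 1e-12)                        # ~6.513e-4 cm^-1
  expect_equal(unname(r$csa_per_height_mass), 61.35 / 120)
  morpho$volumes_cm3["PS"] <- 100
  morpho$total_cm3 <- 100
  r2 <- tendon_muscle_ratios(100, morpho)
  expect_equal(unname(r2$csa_per_volume_cm["total"]), 1e-2)
  r3 <- tendon_muscle_ratios(60, morpho)
  expect_equal(unname(r3$csa_per_height_mass), 0.5)
  morpho$volumes_cm3["AS"] <- 0
  expect_error(tendon_muscle_ratios(60, morpho), "positive")
})
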