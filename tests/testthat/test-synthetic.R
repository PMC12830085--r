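# Phantom generator: layer template, soma mosaic, speckle statistics, motion
# bookkeeping, and longitudinal cell loss.

test_that("zero soma density gives pure layer bands and no cells", {
  spec <- small_spec(density = 0)
  ph <- make_phantom(spec)
  expect_equal(nrow(ph$cells), 0L)
  # pure bands: above the RPE mosaic every depth slice is laterally constant
  for (z in seq(2, 78, by = 4)) {
    slice <- ph$reflectivity$data[, z, ]
    expect_lt(max(slice) - min(slice), 1e-9)
  }
})

test_that("soma counts follow the requested density (Poisson, 3 sigma)", {
  spec <- small_spec(shape = c(96, 96, 96), density = 4407, seed = 42)
  ph <- make_phantom(spec)
  area_mm2 <- prod(spec$shape[c(1, 3)] * spec$pitch_um[c(1, 3)]) / 1e6
  lambda <- 4407 * area_mm2
  expect_gt(nrow(ph$cells), lambda - 3 * sqrt(lambda))
  expect_lt(nrow(ph$cells), lambda + 3 * sqrt(lambda))
  # every centroid inside the volume, radii in the configured range
  expect_true(all(ph$cells$b >= 1 & ph$cells$b <= spec$shape[1]))
  expect_true(all(ph$cells$z >= 1 & ph$cells$z <= spec$shape[2]))
  expect_true(all(ph$cells$x >= 1 & ph$cells$x <= spec$shape[3]))
  expect_true(all(ph$cells$radius_um >= 2.5 & ph$cells$radius_um <= 5))
  # dart throwing keeps centres at least one diameter apart
  d2 <- as.matrix(dist(cbind(ph$cells$b * spec$pitch_um[1],
                             ph$cells$x * spec$pitch_um[3])))
  diag(d2) <- Inf
  sep_req <- outer(ph$cells$radius_um, ph$cells$radius_um, `+`)
  expect_true(all(d2 >= sep_req - 1e-9))
})

test_that("a full 310-um field yields the expected baseline cell count", {
  # 4407 cells/mm2 over 310 x 310 um -> Poisson mean ~ 424
  spec <- phantom_spec(shape = c(256L, 64L, 256L),
                       layer_depths = c(rnfl = 12, ipl = 32, inl = 42,
                                        onl = 53, rpe = 60),
                       pitch_um = c(310 / 256, 1, 310 / 256),
                       soma_density_per_mm2 = 4407, seed = 11)
  ph <- make_phantom(spec)
  lambda <- 4407 * 0.310^2
  expect_equal(lambda, 423.5, tolerance = 0.01)
  expect_gt(nrow(ph$cells), lambda - 3 * sqrt(lambda))
  expect_lt(nrow(ph$cells), lambda + 3 * sqrt(lambda))
})

test_that("make_phantom is deterministic for a fixed seed", {
  ph1 <- make_phantom(small_spec(seed = 7))
  ph2 <- make_phantom(small_spec(seed = 7))
  expect_identical(ph1$cells, ph2$cells)
  expect_identical(ph1$reflectivity$data, ph2$reflectivity$data)
})

test_that("speckle is unit-mean, fully developed, and averages as 1/sqrt(N)", {
  spec <- small_spec(density = 0)
  truth <- make_phantom(spec)
  truth$reflectivity <- oct_volume(array(2.5, dim = spec$shape),
                                   pitch_um = spec$pitch_um)
  s <- add_speckle(truth, 8, alpha = 0, seed = 5)
  f <- s$volumes[[1]]$data / 2.5
  expect_gt(mean(f), 0.97) # unit-mean speckle factor
  expect_lt(mean(f), 1.03)
  # fully developed: C ~ 1 regardless of alpha
  expect_equal(speckle_contrast(s$volumes[[1]]$data), 1, tolerance = 0.02)
  s2 <- add_speckle(truth, 2, alpha = 0.7, seed = 6)
  expect_equal(speckle_contrast(s2$volumes[[1]]$data), 1, tolerance = 0.02)
  # alpha = 0: mean of N iid exponentials has contrast 1/sqrt(N)
  avg <- average_batch(s)
  expect_equal(speckle_contrast(avg$data), 1 / sqrt(8), tolerance = 0.05)
})

test_that("alpha = 1 reproduces identical volumes; alpha maps correlation to alpha^2", {
  spec <- small_spec(density = 0)
  truth <- make_phantom(spec)
  # constant reflectivity so the sample correlation reflects speckle alone
  truth$reflectivity <- oct_volume(array(1, dim = spec$shape),
                                   pitch_um = spec$pitch_um)
  s1 <- add_speckle(truth, 3, alpha = 1, seed = 5)
  expect_identical(s1$volumes[[1]]$data, s1$volumes[[3]]$data)
  for (a in c(0, 0.5, 0.8)) {
    s <- add_speckle(truth, 2, alpha = a, seed = 9)
    # the shared/fresh field mixture has complex field correlation alpha^2,
    # and for circular Gaussian speckle the intensity correlation is the
    # squared field correlation: alpha^4 (checked over >= 1e5 voxels)
    r <- cor(as.numeric(s$volumes[[1]]$data), as.numeric(s$volumes[[2]]$data))
    expect_equal(r, a^4, tolerance = 0.02)
  }
  expect_error(add_speckle(truth, 2, alpha = 1.2), "\\[0, 1\\]")
})

test_that("apply_motion keeps exact bookkeeping and zero motion is identity", {
  spec0 <- small_spec(density = 0, motion = list(
    xz_shift_px = c(0, 0), xz_rot_deg = c(0, 0),
    xy_drift_px = c(0, 0), axial_jitter_px = c(0, 0)))
  truth <- make_phantom(spec0)
  s <- add_speckle(truth, 3, alpha = 0.5, seed = 2)
  mv <- apply_motion(s, spec0, seed = 3)
  expect_identical(mv$series$volumes[[2]]$data, s$volumes[[2]]$data)
  expect_true(all(mv$records[[2]]$stage1_xz == 0))
  # sampled motions are recorded exactly within the requested ranges
  spec1 <- small_spec(density = 0)
  mv2 <- apply_motion(s, spec1, seed = 4)
  r <- mv2$records[[2]]
  expect_true(all(abs(r$stage1_xz[1:2]) <= 4))
  expect_true(abs(r$stage1_xz[3]) <= 1)
  expect_true(all(abs(r$stage2_xy) <= 3))
  expect_length(r$stage3_axial, spec1$shape[1])
  expect_true(all(abs(r$stage3_axial) <= 2))
  # determinism
  mv3 <- apply_motion(s, spec1, seed = 4)
  expect_identical(mv3$records[[3]]$stage3_axial, mv2$records[[3]]$stage3_axial)
  # excessive motion errors out
  spec_big <- small_spec(density = 0,
                         motion = list(xz_shift_px = c(-60, 60),
                                       xz_rot_deg = c(0, 0),
                                       xy_drift_px = c(0, 0),
                                       axial_jitter_px = c(0, 0)))
  expect_error(apply_motion(s, spec_big, seed = 1), "half the volume extent")
})

test_that("applying the inverse displacement recovers the volume within interpolation error", {
  # smooth band-limited volume: linear interpolation can represent it, so the
  # round trip isolates the warp logic from feature sharpness
  set.seed(3)
  raw <- array(rnorm(32 * 96 * 96), dim = c(32, 96, 96))
  for (b in 1:32) raw[b, , ] <- octra:::gauss_smooth(raw[b, , ], 3)
  for (z in 1:96) raw[, z, ] <- octra:::gauss_smooth(raw[, z, ], 3)
  sm <- raw - min(raw)
  v <- oct_volume(sm)
  spec <- small_spec(density = 0, seed = 3)
  mv <- apply_motion(volume_series(list(v, v)), spec, seed = 9)
  tr <- mv$records[[2]]
  # undo in reverse order: axial jitter, then XY, then XZ
  und <- apply_displacement(mv$series$volumes[[2]], displacement_record(
    stage3_axial = -tr$stage3_axial))
  und <- apply_displacement(und, displacement_record(
    stage2_xy = -tr$stage2_xy, stage3_axial = numeric(32)))
  und <- apply_displacement(und, displacement_record(
    stage1_xz = octra:::invert_rigid(tr$stage1_xz[1], tr$stage1_xz[2],
                                     tr$stage1_xz[3]),
    stage3_axial = numeric(32)))
  ok <- vol_mask(und)
  core <- und$data[5:28, 10:86, 10:86]
  ref <- sm[5:28, 10:86, 10:86]
  okc <- ok[5:28, 10:86, 10:86]
  expect_lt(max(abs(core[okc] - ref[okc])) / diff(range(ref)), 0.05)
  # on the structured phantom the residual is small in the RMS sense (the
  # steep layer edges exceed what two linear resamplings can represent
  # pointwise)
  truth <- make_phantom(small_spec(density = 4407, seed = 3))
  vr <- truth$reflectivity
  mv2 <- apply_motion(volume_series(list(vr, vr)), spec, seed = 9)
  tr2 <- mv2$records[[2]]
  und2 <- apply_displacement(mv2$series$volumes[[2]], displacement_record(
    stage3_axial = -tr2$stage3_axial))
  und2 <- apply_displacement(und2, displacement_record(
    stage2_xy = -tr2$stage2_xy, stage3_axial = numeric(32)))
  und2 <- apply_displacement(und2, displacement_record(
    stage1_xz = octra:::invert_rigid(tr2$stage1_xz[1], tr2$stage1_xz[2],
                                     tr2$stage1_xz[3]),
    stage3_axial = numeric(32)))
  ok2 <- vol_mask(und2)[5:28, 5:70, 10:86]
  core2 <- und2$data[5:28, 5:70, 10:86]
  ref2 <- vr$data[5:28, 5:70, 10:86]
  expect_lt(sqrt(mean((core2[ok2] - ref2[ok2])^2)) / diff(range(ref2)), 0.05)
})

test_that("longitudinal cell loss follows the survival schedule", {
  spec <- small_spec(shape = c(96, 96, 96), seed = 10)
  fr <- c(1, 0.977, 0.771, 0.533, 0.382)
  onc <- simulate_onc_series(spec, fr, seed = 20)
  n0 <- nrow(onc[[1]]$truth$cells)
  counts <- vapply(onc, function(tp) nrow(tp$truth$cells), integer(1))
  expect_equal(counts[1], n0)
  # binomial 3-sigma bands around n0 * fraction
  for (t in 2:5) {
    mu <- n0 * fr[t]
    sd3 <- 3 * sqrt(n0 * fr[t] * (1 - fr[t]))
    expect_gt(counts[t], mu - sd3)
    expect_lt(counts[t], mu + sd3)
  }
  # non-increasing and nested removal
  expect_true(all(diff(counts) <= 0))
  # determinism
  onc2 <- simulate_onc_series(spec, fr, seed = 20)
  expect_identical(onc2[[3]]$truth$cells, onc[[3]]$truth$cells)
  # trivial schedule leaves the mosaic alone
  one <- simulate_onc_series(spec, 1.0, seed = 21)
  expect_equal(nrow(one[[1]]$truth$cells), n0)
  expect_error(simulate_onc_series(spec, numeric(0)), "empty")
  expect_error(simulate_onc_series(spec, c(0.5, 0.9)), "non-increasing")
})
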