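# Projections, the three registration stages, displacement application, and
# hierarchical averaging.

test_that("side_projection averages the central B-scans (brute-force oracle)", {
  set.seed(1)
  a <- array(rexp(10 * 6 * 5), dim = c(10, 6, 5))
  v <- oct_volume(a)
  # constant volume -> constant projection
  expect_equal(side_projection(oct_volume(array(3, dim = c(8, 4, 4)))),
               matrix(3, 4, 4))
  # central 4 of 10: centre index 6, window 5..8
  p <- side_projection(v, central_n = 4)
  brute <- apply(a[5:8, , ], c(2, 3), mean)
  expect_equal(p, brute)
  # central_n larger than the volume uses everything
  expect_equal(side_projection(v, central_n = 60), apply(a, c(2, 3), mean))
  # bright plane z = 3 carries the full signal on row 3
  b <- array(0, dim = c(10, 6, 5)); b[, 3, ] <- 7
  expect_equal(side_projection(oct_volume(b))[3, ], rep(7, 5))
  expect_equal(sum(side_projection(oct_volume(b))[-3, ]), 0)
})

test_that("enface_stddev_projection is the population SD over depth", {
  # hand example: z-profile [0, 10] -> population SD 5
  a <- array(0, dim = c(2, 2, 2))
  a[, 2, ] <- 10
  expect_equal(enface_stddev_projection(oct_volume(a)),
               matrix(5, 2, 2))
  # brute-force oracle on a random 4x6x5 volume
  set.seed(2)
  r <- array(rexp(4 * 6 * 5), dim = c(4, 6, 5))
  v <- oct_volume(r)
  brute <- apply(r[, 2:5, ], c(1, 3), function(z) sqrt(mean((z - mean(z))^2)))
  expect_equal(enface_stddev_projection(v, c(2, 5)), brute)
  # constant volume -> zero map; degenerate range errors
  expect_equal(max(enface_stddev_projection(oct_volume(array(1, dim = c(2, 4, 2))))), 0)
  expect_error(enface_stddev_projection(v, c(3, 3)), "at least 2")
})

test_that("phase correlation recovers known shifts", {
  ref <- layered_image(96, 128, seed = 3)
  expect_equal(unname(phase_correlation_shift(ref, ref)), c(0, 0))
  img <- octra:::fill_na_mean(octra:::axis_shift(
    octra:::axis_shift(ref, 1, 5)$data, 2, -3)$data)
  sh <- phase_correlation_shift(img, ref)
  expect_all_lt(sh - c(-5, 3), 0.05)
  img2 <- octra:::fill_na_mean(octra:::axis_shift(ref, 1, 0.5)$data)
  sh2 <- phase_correlation_shift(img2, ref)
  expect_all_lt(sh2 - c(-0.5, 0), 0.1)
  expect_warning(phase_correlation_shift(matrix(1, 8, 8), matrix(1, 8, 8)),
                 "constant")
  expect_error(phase_correlation_shift(matrix(1, 4, 4), matrix(1, 5, 5)),
               "same shape")
})

test_that("rigid_register_xz recovers translation and rotation", {
  ref <- layered_image(128, 256, seed = 4)
  expect_all_lt(rigid_register_xz(ref, ref), 1e-3)
  mv <- octra:::warp_plane_rigid(ref, dx = 3, dz = -2, rot_deg = 0)
  est <- rigid_register_xz(octra:::fill_na_mean(mv$data), ref)
  expect_all_lt(est[1:2] - c(-3, 2), 0.5)
  mv2 <- octra:::warp_plane_rigid(ref, dx = 0, dz = 0, rot_deg = 0.8)
  est2 <- rigid_register_xz(octra:::fill_na_mean(mv2$data), ref)
  expect_lt(abs(est2[3] + 0.8), 0.2)
  expect_warning(rigid_register_xz(matrix(2, 16, 16), matrix(2, 16, 16)),
                 "constant")
})

test_that("reorganize_bscans interleaves B-scan-major and the map restores frames", {
  vols <- lapply(1:2, function(v) {
    a <- array(0, dim = c(3, 2, 2))
    for (b in 1:3) a[b, , ] <- 10 * v + b
    oct_volume(a)
  })
  s <- volume_series(vols)
  ro <- reorganize_bscans(s)
  # order: (v1,b1),(v2,b1),(v1,b2),(v2,b2),(v1,b3),(v2,b3)
  expect_equal(vapply(ro$frames, function(f) f[1, 1], numeric(1)),
               c(11, 21, 12, 22, 13, 23))
  expect_equal(ro$index_map$volume, rep(1:2, 3))
  expect_equal(ro$index_map$bscan, rep(1:3, each = 2))
  # round trip through the index map
  for (i in seq_len(nrow(ro$index_map))) {
    v <- ro$index_map$volume[i]; b <- ro$index_map$bscan[i]
    expect_identical(ro$frames[[i]], s$volumes[[v]]$data[b, , ])
  }
  # single volume keeps its own order
  ro1 <- reorganize_bscans(volume_series(vols[1]))
  expect_equal(vapply(ro1$frames, function(f) f[1, 1], numeric(1)), c(11, 12, 13))
})

test_that("axial_align_bscans recovers known frame shifts", {
  base <- layered_image(96, 96, seed = 5)
  # jitter-free stack -> all zero
  expect_equal(axial_align_bscans(list(base, base, base)), c(0, 0, 0))
  # known shifts: corrections within 0.5 px, exact structure
  shifts <- c(0, 2, -1, 0.5, -2, 1, 0, -0.5)
  frames <- lapply(shifts, function(s) {
    octra:::fill_na_mean(octra:::axis_shift(base, 1, s)$data)
  })
  est <- axial_align_bscans(frames)
  expect_all_lt(est + shifts, 0.5)
  # half the columns displaced +2, half 0 -> mean shift ~ -1 per the rule
  f2 <- base
  f2[, 1:48] <- octra:::fill_na_mean(octra:::axis_shift(base[, 1:48], 1, 2)$data)
  est2 <- axial_align_bscans(list(base, f2))
  expect_equal(est2[2], -1, tolerance = 0.25)
  expect_error(axial_align_bscans(list(base)), "at least 2")
  expect_error(axial_align_bscans(list(base, base[, 1:10])), "mismatched widths")
})

test_that("apply_displacement is identity for a zero record and invertible", {
  set.seed(6)
  a <- array(rexp(16 * 32 * 32), dim = c(16, 32, 32))
  v <- oct_volume(a)
  z <- displacement_record(stage3_axial = numeric(16))
  expect_identical(apply_displacement(v, z)$data, a)
  # mask shrinkage equals the swept border predicted from the shifts
  rec <- displacement_record(stage1_xz = c(0, 3, 0), stage2_xy = c(-2, 0),
                             stage3_axial = numeric(16))
  out <- apply_displacement(v, rec)
  m <- vol_mask(out)
  expect_true(all(!m[, 1:3, ]))   # top 3 z rows swept out
  expect_true(all(!m[, , 31:32])) # last 2 x columns swept out
  expect_true(all(m[, 4:32, 1:30]))
  expect_error(apply_displacement(v, displacement_record(
    stage1_xz = c(40, 0, 0), stage3_axial = numeric(16))), "exceeds")
})

test_that("average_batch is the mask-weighted mean", {
  a <- array(2, dim = c(2, 2, 2)); b <- array(4, dim = c(2, 2, 2))
  s <- volume_series(list(oct_volume(a), oct_volume(b)))
  avg <- average_batch(s)
  expect_equal(avg$data, array(3, dim = c(2, 2, 2)))
  expect_equal(avg$meta$n_members, 2L)
  # identical volumes -> any member
  s2 <- volume_series(list(oct_volume(a), oct_volume(a)))
  expect_equal(average_batch(s2)$data, a)
  # one contributor masked -> the other member's value there
  m <- array(TRUE, dim = c(2, 2, 2)); m[1, 1, 1] <- FALSE
  s3 <- volume_series(list(oct_volume(a, valid_mask = m), oct_volume(b)))
  avg3 <- average_batch(s3)
  expect_equal(avg3$data[1, 1, 1], 4)
  expect_equal(avg3$data[2, 2, 2], 3)
  expect_equal(avg3$meta$contributors[1, 1, 1], 1)
})

test_that("register_batch on a motion-free batch estimates near-zero and logs stages", {
  spec <- phantom_spec(shape = c(64, 128, 192), seed = 12)
  ph <- make_phantom(spec)
  s <- add_speckle(ph, 3, seed = 13)
  withr::local_options(octra.verbose = TRUE)
  msgs <- capture_messages(reg <- register_batch(s, run_config()))
  expect_true(any(grepl("stage1", msgs)))
  expect_true(any(grepl("stage2", msgs)))
  expect_true(any(grepl("stage3", msgs)))
  # estimates sit at the speckle noise floor of the projections (the fresh
  # field component differs between volumes even without motion)
  for (v in 2:3) {
    r <- reg$records[[v]]
    expect_all_lt(r$stage1_xz, 0.5)
    expect_all_lt(r$stage2_xy, 0.5)
    expect_all_lt(r$stage3_axial, 1)
  }
})

test_that("register_batch recovers known synthetic motion", {
  spec <- small_spec(shape = c(48, 96, 192),
                     density = 4407, seed = 14,
                     motion = list(xz_shift_px = c(-4, 4),
                                   xz_rot_deg = c(-0.6, 0.6),
                                   xy_drift_px = c(-3, 3),
                                   axial_jitter_px = c(-1, 1)))
  ph <- make_phantom(spec)
  s <- add_speckle(ph, 4, seed = 15)
  mv <- apply_motion(s, spec, seed = 16)
  reg <- register_batch(mv$series, run_config())
  for (v in 2:4) {
    r <- reg$records[[v]]; tr <- mv$records[[v]]
    expect_lt(abs(r$stage1_xz[3] + tr$stage1_xz[3]), 0.25)
    expect_lt(abs(r$stage1_xz[1] + r$stage2_xy[1] +
                    tr$stage1_xz[1] + tr$stage2_xy[1]), 0.6)
    expect_lt(abs(r$stage1_xz[2] + tr$stage1_xz[2] + mean(tr$stage3_axial)), 0.6)
    expect_lt(abs(r$stage2_xy[2] + tr$stage2_xy[2]), 0.6)
  }
})

test_that("hierarchical averaging of identical volumes equals the flat mean", {
  set.seed(17)
  vols <- lapply(1:12, function(i) {
    oct_volume(array(rexp(8 * 24 * 24), dim = c(8, 24, 24)))
  })
  s <- volume_series(vols)
  flat <- Reduce(`+`, lapply(vols, `[[`, "data")) / 12
  # no registration: mean-of-means equals the flat mean for equal batches
  h <- hierarchical_average(s, run_config(batch_size = 6), register = FALSE)
  expect_lt(max(abs(h$volume$data - flat)), 1e-6)
  # single volume passes through untouched
  h1 <- hierarchical_average(volume_series(vols[1]), run_config())
  expect_identical(h1$volume$data, vols[[1]]$data)
})

test_that("round sizes follow ceiling division down to one volume", {
  expect_equal(octra:::hierarchy_round_sizes(200, 6), c(200, 34, 6, 1))
  expect_equal(octra:::hierarchy_round_sizes(36, 6), c(36, 6, 1))
  expect_equal(octra:::hierarchy_round_sizes(1, 6), 1)
  # exercised end-to-end on a small series: 8 volumes, batch 3 -> 8, 3, 1
  vols <- lapply(1:8, function(i) oct_volume(array(i, dim = c(2, 4, 4))))
  h <- hierarchical_average(volume_series(vols), run_config(batch_size = 3),
                            register = FALSE)
  expect_equal(nrow(h$trail), 0L) # no registration -> empty trail
  # batches of (3,3,2) then (3) -> mean of means, not flat mean
  r1 <- c(mean(1:3), mean(4:6), mean(7:8))
  expect_equal(h$volume$data[1, 1, 1], mean(r1))
})

test_that("averaging never increases speckle contrast", {
  spec <- small_spec(density = 0, seed = 18)
  truth <- make_phantom(spec)
  for (a in c(0, 0.5)) {
    s <- add_speckle(truth, 6, alpha = a, seed = 19)
    c1 <- speckle_contrast(s$volumes[[1]]$data)
    cN <- speckle_contrast(average_batch(s)$data)
    expect_lte(cN, c1)
  }
})

test_that("soma centres stay bright in the registered average when somas decorrelate faster", {
  # alpha inside somas < alpha outside: averaging cleans soma interiors while
  # the surround keeps frozen speckle; soma centre voxels should sit in the
  # top decile of the averaged volume
  spec <- small_spec(shape = c(48, 96, 96), seed = 20,
                     speckle_field_corr = 0.6, soma_field_corr = 0.2)
  ph <- make_phantom(spec)
  s <- add_speckle(ph, 12, seed = 21)
  avg <- hierarchical_average(s, run_config(), register = FALSE)$volume
  thr <- quantile(avg$data, 0.9)
  centre_vals <- vapply(seq_len(nrow(ph$cells)), function(i) {
    avg$data[round(ph$cells$b[i]), round(ph$cells$z[i]), round(ph$cells$x[i])]
  }, numeric(1))
  expect_gte(mean(centre_vals > thr), 0.9)
})
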