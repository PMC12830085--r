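# Shared fixtures, all generated in code.

# Compact layered spec for fast tests: depth 96, somas in z ~ 27-39.
small_spec <- function(shape = c(32, 96, 96), density = 4407, seed = 1,
                       motion = list(xz_shift_px = c(-4, 4),
                                     xz_rot_deg = c(-1, 1),
                                     xy_drift_px = c(-3, 3),
                                     axial_jitter_px = c(-2, 2)),
                       ...) {
  phantom_spec(shape = shape,
               layer_depths = c(rnfl = 18, ipl = 48, inl = 63, onl = 80, rpe = 90),
               soma_density_per_mm2 = density, seed = seed, motion = motion, ...)
}

# Structured side-projection-like image: layered rows + speckle texture.
layered_image <- function(nz = 96, nx = 128, seed = 1) {
  set.seed(seed)
  prof <- c(rep(0.05, round(nz * 0.2)), rep(1, round(nz * 0.12)),
            rep(0.3, round(nz * 0.2)), rep(0.5, round(nz * 0.12)),
            rep(0.15, round(nz * 0.2)))
  prof <- c(prof, rep(0.9, nz - length(prof)))
  outer(prof, rep(1, nx)) * matrix(rexp(nz * nx), nz, nx)
}

# Noise-free volume with planar layer boundaries tilted by `slope_x`
# px/column and `slope_b` px/frame; returns the volume and true surfaces.
tilted_phantom <- function(shape = c(16, 96, 64), slope_x = 0, slope_b = 0,
                           ld = c(rnfl = 18, ipl = 48, inl = 63, onl = 80, rpe = 90)) {
  lvl <- c(0.04, 1, 0.25, 0.5, 0.15, 0.12, 0.9, 0.05)
  gcc <- ld["ipl"] - ld["rnfl"]
  bounds <- c(ld["rnfl"], ld["rnfl"] + 0.3 * gcc, ld["rnfl"] + 0.7 * gcc,
              ld["ipl"], ld["inl"], ld["onl"], ld["rpe"])
  prof_at <- function(z) lvl[findInterval(z, bounds) + 1L]
  vol <- array(0, dim = shape)
  rnfl_z <- matrix(0, shape[1], shape[3])
  ipl_z <- matrix(0, shape[1], shape[3])
  zs <- seq_len(shape[2])
  for (b in seq_len(shape[1])) {
    for (x in seq_len(shape[3])) {
      sh <- slope_x * (x - shape[3] / 2) + slope_b * (b - shape[1] / 2)
      vol[b, , x] <- prof_at(zs - sh)
      rnfl_z[b, x] <- ld["rnfl"] + sh
      ipl_z[b, x] <- ld["ipl"] + sh
    }
  }
  list(vol = oct_volume(vol, pitch_um = c(310 / 512, 1, 310 / 512)),
       rnfl_z = rnfl_z, ipl_z = ipl_z)
}

expect_all_lt <- function(x, bound) {
  expect_lt(max(abs(x)), bound)
}
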