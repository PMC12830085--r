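# Synthetic retinal phantom: layered reflectivity, soma mosaics, partially
# decorrelated multiplicative speckle, rigid/lateral/axial motion, and
# longitudinal cell loss. Every downstream stage is validated against the
# ground truth this module records.

#' Phantom specification
#'
#' Describes a synthetic retinal volume: grid shape, layer boundary depths,
#' soma mosaic, speckle decorrelation, and motion ranges.
#'
#' The speckle model is multiplicative on reflectivity: volume `v` has
#' intensity `I_v = R * |alpha*A + sqrt(1-alpha^2)*B_v|^2` with `A` a shared
#' and `B_v` a per-volume fresh unit-variance circular complex Gaussian field,
#' so the speckle factor has unit mean and the inter-volume intensity
#' correlation is `alpha^2`. `speckle_field_corr` applies outside somas;
#' `soma_field_corr` (lower, mimicking organelle motility as an intrinsic
#' contrast agent) applies inside soma interiors, so averaging converges to a
#' clean, homogeneous hyperreflective soma against a residually speckled
#' surround.
#'
#' @param shape integer `c(n_bscans, depth, n_ascans)`.
#' @param layer_depths strictly increasing named depths (voxels) of the five
#'   boundaries: anterior RNFL, posterior IPL, posterior INL, posterior ONL,
#'   posterior RPE.
#' @param soma_diameter_um soma diameter range in micrometres (default 5-10,
#'   the mouse RGC soma range).
#' @param soma_density_per_mm2 target planar soma density in the ganglion cell
#'   layer (default 4407, a typical mid-superior mouse retina value).
#' @param speckle_field_corr alpha in `[0, 1]`: inter-volume speckle field
#'   correlation outside somas.
#' @param soma_field_corr alpha inside soma interiors.
#' @param motion list of uniform sampling ranges: `xz_shift_px` (B-scan-plane
#'   shift, both axes), `xz_rot_deg`, `xy_drift_px` (en face drift, both
#'   axes), `axial_jitter_px` (per-B-scan).
#' @param pitch_um voxel pitch `c(b, z, x)` in micrometres.
#' @param seed integer seed used by [make_phantom()].
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 128L, 128L),
                         layer_depths = c(rnfl = 24, ipl = 64, inl = 84,
                                          onl = 106, rpe = 120),
                         soma_diameter_um = c(5, 10),
                         soma_density_per_mm2 = 4407,
                         speckle_field_corr = 0.6,
                         soma_field_corr = 0.2,
                         motion = list(xz_shift_px = c(-4, 4),
                                       xz_rot_deg = c(-1, 1),
                                       xy_drift_px = c(-3, 3),
                                       axial_jitter_px = c(-2, 2)),
                         pitch_um = c(310 / 512, 1, 310 / 512),
                         seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 4L))
  layer_depths <- as.numeric(layer_depths)
  if (length(layer_depths) != 5L || any(diff(layer_depths) <= 0) ||
      layer_depths[1] < 2 || layer_depths[5] > shape[2]) {
    stop("`layer_depths` must be 5 strictly increasing depths within the volume")
  }
  names(layer_depths) <- c("rnfl", "ipl", "inl", "onl", "rpe")
  if (any(soma_diameter_um <= 0) || length(soma_diameter_um) != 2L) {
    stop("`soma_diameter_um` must be a positive range")
  }
  for (a in c(speckle_field_corr, soma_field_corr)) {
    if (a < 0 || a > 1) stop("field correlations must lie in [0, 1]")
  }
  structure(list(
    shape = shape, layer_depths = layer_depths,
    soma_diameter_um = as.numeric(soma_diameter_um),
    soma_density_per_mm2 = as.numeric(soma_density_per_mm2),
    speckle_field_corr = as.numeric(speckle_field_corr),
    soma_field_corr = as.numeric(soma_field_corr),
    motion = motion, pitch_um = as.numeric(pitch_um), seed = as.integer(seed)
  ), class = "phantom_spec")
}

# Reflectivity levels of the layer template. The soma/neuropil ratio is not a
# measured quantity; levels are chosen so somas are invisible in a single
# speckled volume (CNR < 1) and clearly resolved after ~dozens of averages.
phantom_levels <- function() {
  list(vitreous = 0.04, rnfl = 1.0, gcl = 0.25, ipl = 0.5, inl = 0.15,
       onl = 0.12, rpe = 0.9, below = 0.05, soma = 1.3, rpe_disc = 0.15)
}

# Smooth piecewise-constant axial reflectivity profile and the z-bands of the
# ganglion cell layer (where somas live) and the RPE.
phantom_layers <- function(spec) {
  d <- spec$shape
  L <- spec$layer_depths
  lv <- phantom_levels()
  gcc <- L["ipl"] - L["rnfl"]
  z_rnfl_end <- L["rnfl"] + 0.3 * gcc
  z_gcl_end <- L["rnfl"] + 0.7 * gcc
  z <- seq_len(d[2])
  prof <- rep(lv$vitreous, d[2])
  prof[z >= L["rnfl"] & z < z_rnfl_end] <- lv$rnfl
  prof[z >= z_rnfl_end & z < z_gcl_end] <- lv$gcl
  prof[z >= z_gcl_end & z < L["ipl"]] <- lv$ipl
  prof[z >= L["ipl"] & z < L["inl"]] <- lv$inl
  prof[z >= L["inl"] & z < L["onl"]] <- lv$onl
  prof[z >= L["onl"] & z < L["rpe"]] <- lv$rpe
  prof[z >= L["rpe"]] <- lv$below
  # mild axial smoothing so boundaries are steep but not aliased
  k <- exp(-(-3:3)^2 / (2 * 1.0^2))
  k <- k / sum(k)
  prof <- as.numeric(stats::filter(c(rep(prof[1], 3), prof, rep(prof[d[2]], 3)),
                                   k, sides = 2))[4:(d[2] + 3)]
  list(profile = prof,
       gcl_band = c(ceiling(z_rnfl_end) + 1, floor(z_gcl_end) - 1),
       rpe_band = c(ceiling(L["onl"]), floor(L["rpe"]) - 1))
}

# Dart-throwing placement of soma centres in the en face plane with a
# minimum centre separation of one diameter.
place_somas <- function(spec, gcl_band) {
  d <- spec$shape
  area_mm2 <- (d[1] * spec$pitch_um[1]) * (d[3] * spec$pitch_um[3]) / 1e6
  n_target <- stats::rpois(1, spec$soma_density_per_mm2 * area_mm2)
  if (n_target == 0L) {
    return(data.frame(b = numeric(0), z = numeric(0), x = numeric(0),
                      radius_um = numeric(0)))
  }
  cb <- numeric(n_target); cx <- numeric(n_target)
  cz <- numeric(n_target); rad <- numeric(n_target)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 200L * n_target
  z_mid <- mean(gcl_band)
  z_half <- max(0, (gcl_band[2] - gcl_band[1]) / 2 - 1)
  while (placed < n_target && attempts < max_attempts) {
    attempts <- attempts + 1L
    r_um <- runif(1, spec$soma_diameter_um[1], spec$soma_diameter_um[2]) / 2
    rb <- r_um / spec$pitch_um[1]
    rx <- r_um / spec$pitch_um[3]
    if (1 + rb >= d[1] - rb || 1 + rx >= d[3] - rx) {
      stop("volume laterally too small to contain a soma of diameter ",
           signif(2 * r_um, 3), " um")
    }
    b <- runif(1, 1 + rb, d[1] - rb)
    x <- runif(1, 1 + rx, d[3] - rx)
    if (placed > 0L) {
      db_um <- (cb[1:placed] - b) * spec$pitch_um[1]
      dx_um <- (cx[1:placed] - x) * spec$pitch_um[3]
      sep_um <- sqrt(db_um^2 + dx_um^2)
      min_sep <- rad[1:placed] + r_um # one diameter for equal radii
      if (any(sep_um < min_sep)) next
    }
    placed <- placed + 1L
    cb[placed] <- b
    cx[placed] <- x
    cz[placed] <- z_mid + runif(1, -z_half / 2, z_half / 2)
    rad[placed] <- r_um
  }
  if (placed < n_target) {
    stop(sprintf(
      "soma density too high: placed %d of %d cells without overlap", placed, n_target
    ))
  }
  data.frame(b = cb[1:placed], z = cz[1:placed], x = cx[1:placed],
             radius_um = rad[1:placed])
}

# Paint soft-edged ellipsoidal somas into reflectivity and set their interior
# speckle correlation.
paint_somas <- function(refl, alpha, cells, spec) {
  lv <- phantom_levels()
  d <- dim(refl)
  p <- spec$pitch_um
  for (i in seq_len(nrow(cells))) {
    r_um <- cells$radius_um[i]
    rb <- r_um / p[1]; rz <- r_um / p[2]; rx <- r_um / p[3]
    bb <- max(1, floor(cells$b[i] - rb)):min(d[1], ceiling(cells$b[i] + rb))
    zz <- max(1, floor(cells$z[i] - rz)):min(d[2], ceiling(cells$z[i] + rz))
    xx <- max(1, floor(cells$x[i] - rx)):min(d[3], ceiling(cells$x[i] + rx))
    db <- (bb - cells$b[i]) / rb
    dz <- (zz - cells$z[i]) / rz
    dx <- (xx - cells$x[i]) / rx
    rho2 <- outer(outer(db^2, dz^2, `+`), dx^2, `+`)
    w <- pmin(1, pmax(0, (1 - rho2) / 0.36)) # soft shell over outer 36% of r^2
    cur <- refl[bb, zz, xx]
    refl[bb, zz, xx] <- pmax(cur, lv$soma * w)
    am <- alpha[bb, zz, xx]
    am[rho2 <= 1] <- spec$soma_field_corr
    alpha[bb, zz, xx] <- am
  }
  list(refl = refl, alpha = alpha)
}

# Regular mosaic of hyporeflective discs (nuclei) in the hyperreflective RPE
# band.
paint_rpe <- function(refl, rpe_band, spec, spacing_um = 15, radius_um = 3.5) {
  d <- dim(refl)
  p <- spec$pitch_um
  lv <- phantom_levels()
  if (d[1] * p[1] < spacing_um || d[3] * p[3] < spacing_um) return(refl)
  bs <- seq(spacing_um / 2, d[1] * p[1] - spacing_um / 2, by = spacing_um) / p[1]
  xs <- seq(spacing_um / 2, d[3] * p[3] - spacing_um / 2, by = spacing_um) / p[3]
  zz <- rpe_band[1]:rpe_band[2]
  bg <- rep(seq_len(d[1]), times = d[3])
  xg <- rep(seq_len(d[3]), each = d[1])
  inside <- matrix(FALSE, d[1], d[3])
  for (cb in bs) {
    for (cx in xs) {
      jb <- cb + runif(1, -1, 1)
      jx <- cx + runif(1, -1, 1)
      db_um <- (bg - jb) * p[1]
      dx_um <- (xg - jx) * p[3]
      inside <- inside | matrix(db_um^2 + dx_um^2 <= radius_um^2, d[1], d[3])
    }
  }
  idx <- which(inside, arr.ind = TRUE)
  for (z in zz) refl[cbind(idx[, 1], z, idx[, 2])] <- lv$rpe_disc
  refl
}

#' Generate a phantom volume with ground truth
#'
#' Builds the noise-free layered reflectivity volume, places the soma mosaic
#' in the ganglion cell layer and the hyporeflective disc mosaic in the RPE,
#' and records every placement: cell centroids and radii, true layer
#' surfaces, and the per-voxel speckle correlation map.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_truth` with fields `reflectivity`
#'   ([oct_volume]), `cells` (data frame `b, z, x, radius_um`), `surfaces`
#'   ([layer_surface_pair]), `alpha` (per-voxel field correlation array),
#'   `applied_motion` (filled by [apply_motion()]), and `spec`.
#' @examples
#' spec <- phantom_spec(shape = c(16, 64, 32), soma_density_per_mm2 = 0)
#' ph <- make_phantom(spec)
#' nrow(ph$cells)
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  d <- spec$shape
  lay <- phantom_layers(spec)
  refl <- array(rep(lay$profile, each = d[1]), dim = d)
  alpha <- array(spec$speckle_field_corr, dim = d)
  cells <- place_somas(spec, lay$gcl_band)
  if (nrow(cells) > 0) {
    pt <- paint_somas(refl, alpha, cells, spec)
    refl <- pt$refl
    alpha <- pt$alpha
  }
  refl <- paint_rpe(refl, lay$rpe_band, spec)
  surf <- layer_surface_pair(
    rnfl_z = matrix(spec$layer_depths["rnfl"], d[1], d[3]),
    ipl_z = matrix(spec$layer_depths["ipl"], d[1], d[3]),
    axial_pitch_um = spec$pitch_um[2]
  )
  structure(list(
    reflectivity = oct_volume(refl, pitch_um = spec$pitch_um,
                              meta = list(phantom_seed = spec$seed)),
    cells = cells, surfaces = surf, alpha = alpha,
    applied_motion = NULL, spec = spec
  ), class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  d <- dim(x$reflectivity$data)
  cat(sprintf("<phantom_truth> %d x %d x %d, %d somas\n",
              d[1], d[2], d[3], nrow(x$cells)))
  invisible(x)
}

#' Add partially decorrelated speckle to a phantom
#'
#' Each volume `v` gets intensity `I_v = R * |alpha*A + sqrt(1-alpha^2)*B_v|^2`
#' where `A` is one shared and `B_v` a fresh unit-variance circular complex
#' Gaussian field. The speckle factor has unit mean; a single volume over
#' constant reflectivity is fully developed speckle (exponential intensity,
#' contrast 1), and `alpha^2` is the inter-volume intensity correlation.
#'
#' @param truth a [make_phantom()] result.
#' @param n_volumes number of volumes to synthesize.
#' @param alpha field correlation: `NULL` to use the phantom's per-voxel map,
#'   or a scalar in `[0, 1]` applied everywhere.
#' @param seed integer seed.
#' @return A [volume_series].
#' @export
add_speckle <- function(truth, n_volumes, alpha = NULL, seed = 1L) {
  stopifnot(inherits(truth, "phantom_truth"), n_volumes >= 1)
  R <- truth$reflectivity$data
  d <- dim(R)
  if (is.null(alpha)) {
    a <- truth$alpha
  } else {
    if (length(alpha) != 1L || alpha < 0 || alpha > 1) {
      stop("`alpha` must be a scalar in [0, 1]")
    }
    a <- alpha
  }
  set.seed(seed)
  n <- prod(d)
  s <- 1 / sqrt(2)
  A <- complex(real = rnorm(n, 0, s), imaginary = rnorm(n, 0, s))
  beta <- sqrt(1 - a^2)
  vols <- vector("list", n_volumes)
  for (v in seq_len(n_volumes)) {
    B <- complex(real = rnorm(n, 0, s), imaginary = rnorm(n, 0, s))
    f <- Mod(a * A + beta * B)^2
    vols[[v]] <- oct_volume(array(R * f, dim = d), pitch_um = truth$reflectivity$pitch_um,
                            meta = list(speckle_seed = seed, volume = v))
  }
  volume_series(vols)
}

# Shared volume mover: B-scan-plane rigid transform, then en face translation,
# then per-B-scan axial shift, with the valid mask tracking every voxel whose
# source left the original grid.
move_volume <- function(data, mask, xz = c(0, 0, 0), xy = c(0, 0),
                        axial = NULL) {
  d <- dim(data)
  work <- data
  work[!mask] <- NA_real_
  if (any(xz != 0)) {
    for (b in seq_len(d[1])) {
      work[b, , ] <- warp_plane_rigid(work[b, , ], dx = xz[1], dz = xz[2],
                                      rot_deg = xz[3])$data
    }
  }
  if (xy[1] != 0) work <- axis_shift(work, 3, xy[1])$data
  if (xy[2] != 0) work <- axis_shift(work, 1, xy[2])$data
  if (!is.null(axial) && any(axial != 0)) {
    for (b in seq_len(d[1])) {
      if (axial[b] != 0) {
        work[b, , ] <- axis_shift(work[b, , , drop = FALSE], 2, axial[b])$data
      }
    }
  }
  new_mask <- !is.na(work)
  work[!new_mask] <- 0
  list(data = work, mask = new_mask)
}

#' Apply sampled rigid, lateral and axial motion to a series
#'
#' The first volume is the reference and stays put. Every later volume
#' receives a rigid B-scan-plane (XZ) shift and rotation, an en face (XY)
#' drift, and independent per-B-scan axial jitter, all sampled uniformly
#' within the ranges in `spec$motion`. Voxels moved in from outside the grid
#' are flagged invalid.
#'
#' @param series a [volume_series].
#' @param spec a [phantom_spec()] providing the motion ranges.
#' @param seed integer seed.
#' @return list with `series` (moved volumes) and `records` (one ground-truth
#'   [displacement_record] per volume; applied motions, not corrections).
#' @export
apply_motion <- function(series, spec, seed = 1L) {
  stopifnot(inherits(series, "volume_series"), length(series$volumes) >= 1)
  d <- dim(series$volumes[[1]]$data)
  mo <- spec$motion
  chk <- function(r, half, what) {
    if (max(abs(r)) >= half) stop("requested ", what, " exceeds half the volume extent")
  }
  chk(mo$xz_shift_px, min(d[2], d[3]) / 2, "XZ shift")
  chk(mo$xy_drift_px, min(d[1], d[3]) / 2, "XY drift")
  chk(mo$axial_jitter_px, d[2] / 2, "axial jitter")
  set.seed(seed)
  n_b <- d[1]
  out <- series$volumes
  recs <- vector("list", length(out))
  recs[[1]] <- displacement_record(stage3_axial = numeric(n_b))
  for (v in seq_along(out)[-1]) {
    xz <- c(runif(1, mo$xz_shift_px[1], mo$xz_shift_px[2]),
            runif(1, mo$xz_shift_px[1], mo$xz_shift_px[2]),
            runif(1, mo$xz_rot_deg[1], mo$xz_rot_deg[2]))
    xy <- c(runif(1, mo$xy_drift_px[1], mo$xy_drift_px[2]),
            runif(1, mo$xy_drift_px[1], mo$xy_drift_px[2]))
    jit <- runif(n_b, mo$axial_jitter_px[1], mo$axial_jitter_px[2])
    vol <- out[[v]]
    mv <- move_volume(vol$data, vol_mask(vol), xz = xz, xy = xy, axial = jit)
    out[[v]] <- oct_volume(mv$data, pitch_um = vol$pitch_um,
                           valid_mask = mv$mask, meta = vol$meta)
    recs[[v]] <- displacement_record(stage1_xz = xz, stage2_xy = xy,
                                     stage3_axial = jit)
  }
  list(series = volume_series(out, series$acquisition_index), records = recs)
}

#' Simulate a longitudinal cell-loss series
#'
#' Reuses one baseline soma mosaic and removes a nested random subset of
#' cells at each timepoint so the surviving fraction matches the requested
#' schedule in expectation (binomial thinning, survivors at each timepoint a
#' subset of the previous). Speckle is regenerated per timepoint; motion is
#' optionally re-applied.
#'
#' @param spec a [phantom_spec()].
#' @param survival_fractions numeric in `(0, 1]`, non-increasing, one per
#'   timepoint (first is the baseline).
#' @param seed integer seed.
#' @param n_volumes volumes per timepoint series.
#' @param with_motion apply sampled motion to each timepoint's series.
#' @return list of per-timepoint entries: `timepoint`, `fraction`, `series`
#'   ([volume_series]), `truth` ([make_phantom]-style truth restricted to the
#'   surviving cells).
#' @export
simulate_onc_series <- function(spec, survival_fractions, seed = 1L,
                                n_volumes = 1L, with_motion = FALSE) {
  if (length(survival_fractions) < 1L) stop("empty survival fraction list")
  if (any(survival_fractions <= 0 | survival_fractions > 1)) {
    stop("survival fractions must lie in (0, 1]")
  }
  if (any(diff(survival_fractions) > 0)) {
    stop("survival fractions must be non-increasing")
  }
  base <- make_phantom(spec)
  set.seed(seed)
  n0 <- nrow(base$cells)
  # all thinning draws up front so later seeded stages cannot perturb them
  thin_u <- matrix(runif(max(n0, 1) * length(survival_fractions)), ncol = length(survival_fractions))
  alive <- rep(TRUE, n0)
  prev_f <- 1
  out <- vector("list", length(survival_fractions))
  lay <- phantom_layers(spec)
  for (t in seq_along(survival_fractions)) {
    f <- survival_fractions[t]
    if (f < prev_f && n0 > 0) {
      keep_p <- f / prev_f
      alive <- alive & (thin_u[seq_len(n0), t] < keep_p)
      prev_f <- f
    }
    cells_t <- base$cells[alive, , drop = FALSE]
    refl <- array(rep(lay$profile, each = spec$shape[1]), dim = spec$shape)
    alpha <- array(spec$speckle_field_corr, dim = spec$shape)
    if (nrow(cells_t) > 0) {
      pt <- paint_somas(refl, alpha, cells_t, spec)
      refl <- pt$refl
      alpha <- pt$alpha
    }
    set.seed(spec$seed) # RPE mosaic identical across timepoints
    refl <- paint_rpe(refl, lay$rpe_band, spec)
    truth_t <- structure(list(
      reflectivity = oct_volume(refl, pitch_um = spec$pitch_um),
      cells = cells_t, surfaces = base$surfaces, alpha = alpha,
      applied_motion = NULL, spec = spec
    ), class = "phantom_truth")
    series_t <- add_speckle(truth_t, n_volumes, seed = seed + 1000L + t)
    if (with_motion) {
      mv <- apply_motion(series_t, spec, seed = seed + 2000L + t)
      series_t <- mv$series
      truth_t$applied_motion <- mv$records
    }
    out[[t]] <- list(timepoint = t, fraction = f, series = series_t,
                     truth = truth_t)
  }
  out
}
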