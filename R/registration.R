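# Three-stage registration and hierarchical batch averaging. Stage 1 removes
# gross rigid B-scan-plane (XZ) misalignment estimated on side projections;
# stage 2 removes sub-pixel en face (XY) drift by phase correlation of
# standard-deviation projections; stage 3 removes per-B-scan axial jitter by
# column-wise cross-correlation along the reorganized B-scan stack. Batches
# are then averaged, and rounds repeat on the batch averages until a single
# speckle-suppressed volume remains.

#' Side projection of a volume (mean over central B-scans)
#'
#' Averages the central `central_n` B-scans (fewer when the volume is
#' shallower), producing the `z` by `x` image used by stage-1 rigid
#' registration. Invalid voxels are excluded from the mean.
#'
#' @param vol an [oct_volume].
#' @param central_n number of central B-scans to average (default 60).
#' @return matrix `(z, x)`.
#' @export
side_projection <- function(vol, central_n = 60L) {
  stopifnot(inherits(vol, "oct_volume"), central_n >= 1)
  d <- dim(vol$data)
  if (any(d == 0L)) stop("empty volume")
  k <- min(central_n, d[1])
  centre <- d[1] %/% 2 + 1L
  lo <- centre - (k - 1L) %/% 2
  lo <- min(max(lo, 1L), d[1] - k + 1L)
  idx <- lo:(lo + k - 1L)
  dat <- vol$data[idx, , , drop = FALSE]
  if (is.null(vol$valid_mask)) {
    proj <- colMeans(dat, dims = 1)
  } else {
    msk <- vol$valid_mask[idx, , , drop = FALSE]
    num <- colSums(dat * msk, dims = 1)
    den <- colSums(msk, dims = 1)
    proj <- num / pmax(den, 1)
    proj[den == 0] <- NA_real_
  }
  proj
}

#' En face standard-deviation projection
#'
#' Per `(b, x)`, the population standard deviation of intensity over the
#' inclusive depth range, producing the `b` by `x` image used by stage-2
#' phase correlation.
#'
#' @param vol an [oct_volume].
#' @param depth_range inclusive `c(z_lo, z_hi)`, or `NULL` for full depth.
#' @return matrix `(b, x)`.
#' @export
enface_stddev_projection <- function(vol, depth_range = NULL) {
  stopifnot(inherits(vol, "oct_volume"))
  d <- dim(vol$data)
  if (is.null(depth_range)) depth_range <- c(1L, d[2])
  z0 <- depth_range[1]
  z1 <- depth_range[2]
  if (z0 < 1 || z1 > d[2] || (z1 - z0 + 1) < 2) {
    stop("depth range must contain at least 2 samples inside the volume")
  }
  slab <- vol$data[, z0:z1, , drop = FALSE]
  if (is.null(vol$valid_mask)) {
    mu <- colMeans(aperm(slab, c(2, 1, 3)))
    mu2 <- colMeans(aperm(slab^2, c(2, 1, 3)))
    return(sqrt(pmax(mu2 - mu^2, 0)))
  }
  # masked projection: invalid voxels (e.g. border fill after correction)
  # would otherwise imprint artificial high-SD stripes that later stages
  # would lock onto
  msk <- vol$valid_mask[, z0:z1, , drop = FALSE]
  cnt <- colSums(aperm(msk, c(2, 1, 3)))
  s1 <- colSums(aperm(slab * msk, c(2, 1, 3)))
  s2 <- colSums(aperm(slab^2 * msk, c(2, 1, 3)))
  mu <- s1 / pmax(cnt, 1)
  out <- sqrt(pmax(s2 / pmax(cnt, 1) - mu^2, 0))
  out[cnt < 2] <- NA_real_
  out
}

#' Sub-pixel translation by phase correlation
#'
#' Estimates the translation that aligns `img` to `ref` from the peak of the
#' inverse cross-power spectrum, refined to sub-pixel precision by local
#' upsampled DFT evaluation. The return value is the CORRECTION: translating
#' the content of `img` by it maximizes alignment with `ref`.
#'
#' @param img,ref equal-size matrices.
#' @param upsample sub-pixel refinement factor (default 50, i.e. 0.02 px).
#' @return named numeric `c(d1, d2)`: correction along (rows, cols).
#' @export
phase_correlation_shift <- function(img, ref, upsample = 50L) {
  if (!identical(dim(img), dim(ref))) stop("images must have the same shape")
  img <- fill_na_mean(img)
  ref <- fill_na_mean(ref)
  if (stats::sd(img) == 0 || stats::sd(ref) == 0) {
    warning("constant image: returning zero shift")
    return(c(d1 = 0, d2 = 0))
  }
  pc <- cross_power(img, ref)
  peak_int <- int_peak(pc$corr)
  delta <- dft_refine(pc$R, peak_int, upsample, dim(img))
  -(peak_int + delta) # displacement of img -> correction is its negation
}

# Normalized cross-power spectrum and its (real) inverse transform. A Hann
# window suppresses the spectral leakage of the non-periodic image borders,
# which otherwise biases sub-pixel peak localization. The whitened spectrum is
# band-limited with a Gaussian weight: after whitening, every frequency votes
# with equal strength, but in speckled OCT projections the frequencies above
# the structural band carry only decorrelated speckle phase, so an unweighted
# peak search can lock onto noise. `lowpass_sigma` is in cycles/px.
cross_power <- function(img, ref, lowpass_sigma = 0.15) {
  w <- hann2d(dim(img))
  F1 <- fft((img - mean(img)) * w)
  F2 <- fft((ref - mean(ref)) * w)
  R <- F1 * Conj(F2)
  mag <- Mod(R)
  R <- R / pmax(mag, max(mag) * 1e-12)
  if (is.finite(lowpass_sigma) && lowpass_sigma > 0) {
    d <- dim(img)
    f1 <- c(0:(ceiling(d[1] / 2) - 1), -(floor(d[1] / 2)):-1) / d[1]
    f2 <- c(0:(ceiling(d[2] / 2) - 1), -(floor(d[2] / 2)):-1) / d[2]
    W <- exp(-outer(f1^2, f2^2, `+`) / (2 * lowpass_sigma^2))
    R <- R * W
  }
  corr <- Re(fft(R, inverse = TRUE)) / length(R)
  list(R = R, corr = corr)
}

hann2d <- function(d) {
  h <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  outer(h(d[1]), h(d[2]))
}

# Peak normalized cross-correlation over all translations (Hann-windowed,
# demeaned). Used to gate corrections: two projections that share no real
# structure (e.g. fully decorrelated speckle) score near the noise floor
# ~1/sqrt(n_pixels), while genuinely corresponding projections score far
# higher, so estimates below `min_score` are discarded as untrustworthy.
ncc_score <- function(img, ref) {
  w <- hann2d(dim(img))
  a <- (img - mean(img)) * w
  b <- (ref - mean(ref)) * w
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  cc <- Re(fft(fft(a) * Conj(fft(b)), inverse = TRUE)) / length(a)
  max(cc) / (na * nb)
}

# Integer displacement at the correlation peak, unwrapped to signed shifts.
int_peak <- function(corr) {
  d <- dim(corr)
  p <- which(corr == max(corr), arr.ind = TRUE)[1, ]
  s <- p - 1
  s <- ifelse(s > d / 2, s - d, s)
  as.numeric(s)
}

# Local upsampled evaluation of the inverse DFT of the cross-power spectrum
# around an integer peak (matrix-multiply DFT over a +-1 px neighbourhood).
dft_refine <- function(R, peak, usf, d) {
  n1 <- d[1]; n2 <- d[2]
  k1 <- c(0:(ceiling(n1 / 2) - 1), -(floor(n1 / 2)):-1) / n1
  k2 <- c(0:(ceiling(n2 / 2) - 1), -(floor(n2 / 2)):-1) / n2
  off <- seq(-1, 1, by = 1 / usf)
  e1 <- exp(2i * pi * outer(off + peak[1], k1))  # (trial shifts) x k1
  e2 <- exp(2i * pi * outer(k2, off + peak[2]))  # k2 x (trial shifts)
  # correlation at shift s = sum_k R[k] exp(+2 pi i k.s)
  surf <- Re(e1 %*% R %*% e2)
  p <- which(surf == max(surf), arr.ind = TRUE)[1, ]
  c(off[p[1]], off[p[2]])
}

#' Rigid B-scan-plane registration (translation + rotation)
#'
#' Finds the rigid correction aligning `img` to `ref`: rotation by a bounded
#' scan over a discrete angle grid (phase-correlation peak height as the
#' similarity score), translation by sub-pixel phase correlation at the best
#' angle. Applying the returned `(dx, dz, rot_deg)` to `img` (rotate about the
#' centre, then translate) aligns it with `ref`.
#'
#' @param img,ref equal-size `(z, x)` matrices.
#' @param rot_range_deg half-range of the angle scan (default 2).
#' @param rot_step_deg angle scan step (default 0.1).
#' @param min_score minimum normalized-correlation score; below it the images
#'   share no usable structure and the zero transform is returned with a
#'   warning rather than a noise-locked estimate.
#' @return named numeric `c(dx, dz, rot_deg)`.
#' @export
rigid_register_xz <- function(img, ref, rot_range_deg = 2, rot_step_deg = 0.1,
                              min_score = 0.35) {
  if (!identical(dim(img), dim(ref))) stop("images must have the same shape")
  img <- fill_na_mean(img)
  ref <- fill_na_mean(ref)
  if (stats::sd(img) == 0 || stats::sd(ref) == 0) {
    warning("constant image: returning zero transform")
    return(c(dx = 0, dz = 0, rot_deg = 0))
  }
  # pre-smooth so the low-pass effect of interpolated resampling is the same
  # at every trial angle (an unsmoothed zero-angle image would otherwise carry
  # more speckle energy and bias the scan away from 0)
  img <- gauss_smooth(img, 1.5)
  ref <- gauss_smooth(ref, 1.5)
  angles <- seq(-rot_range_deg, rot_range_deg, by = rot_step_deg)
  best <- list(score = -Inf, angle = 0, rot_img = img)
  # angle scan maximizes the (translation-searched) normalized correlation;
  # unlike the whitened phase-correlation peak this weights structure by its
  # energy and is robust to speckle
  wnd <- hann2d(dim(ref))
  refw <- (ref - mean(ref)) * wnd
  Fref <- Conj(fft(refw))
  refn <- sqrt(sum(refw^2))
  scores <- numeric(length(angles))
  for (ai in seq_along(angles)) {
    a <- angles[ai]
    ri <- if (a == 0) img else {
      w <- warp_plane_rigid(img, rot_deg = a)
      fill_na_mean(w$data)
    }
    riw <- (ri - mean(ri)) * wnd
    cc <- Re(fft(fft(riw) * Fref, inverse = TRUE)) / length(riw)
    scores[ai] <- max(cc) / (refn * sqrt(sum(riw^2)))
    if (scores[ai] > best$score) {
      best <- list(score = scores[ai], angle = a, rot_img = ri)
    }
  }
  if (best$score < min_score) {
    octra_log("rigid XZ: no usable shared structure (score %.3f), zero transform",
              best$score)
    return(c(dx = 0, dz = 0, rot_deg = 0))
  }
  # parabolic sub-step refinement of the angle (estimate only; the applied
  # image for the translation step stays on the scanned grid)
  bi <- which.max(scores)
  ang <- angles[bi]
  if (bi > 1 && bi < length(angles)) {
    y0 <- scores[bi - 1]; y1 <- scores[bi]; y2 <- scores[bi + 1]
    den <- y0 - 2 * y1 + y2
    if (den < 0) ang <- ang + rot_step_deg * 0.5 * (y0 - y2) / den
  }
  sh <- phase_correlation_shift(best$rot_img, ref)
  c(dx = unname(sh[2]), dz = unname(sh[1]), rot_deg = ang)
}

#' Reorganize a batch into a B-scan-major frame stack
#'
#' Spatially corresponding B-scans from sequential volumes are interleaved
#' into one continuous stack: all first B-scans (in volume order), then all
#' second B-scans, and so on.
#'
#' @param batch a [volume_series].
#' @return list with `frames` (list of `(z, x)` matrices) and `index_map`
#'   (data frame `frame, volume, bscan`).
#' @export
reorganize_bscans <- function(batch) {
  stopifnot(inherits(batch, "volume_series"))
  if (length(batch$volumes) == 0L) stop("empty batch")
  d <- dim(batch$volumes[[1]]$data)
  n_v <- length(batch$volumes)
  frames <- vector("list", n_v * d[1])
  map <- data.frame(frame = seq_len(n_v * d[1]), volume = 0L, bscan = 0L)
  i <- 0L
  for (b in seq_len(d[1])) {
    for (v in seq_len(n_v)) {
      i <- i + 1L
      frames[[i]] <- batch$volumes[[v]]$data[b, , ]
      map$volume[i] <- v
      map$bscan[i] <- b
    }
  }
  list(frames = frames, index_map = map)
}

#' Axial alignment of a B-scan frame stack
#'
#' Each frame is aligned to its immediately preceding (already aligned) frame:
#' per-column (A-line) 1-D cross-correlation estimates local vertical
#' displacements, the mean over columns passing a validity check gives the
#' frame's single axial shift, and shifts accumulate along the stack.
#'
#' @param frames list of equal-width `(z, x)` matrices (length >= 2).
#' @param max_lag half-width of the per-column lag search in px (default 8).
#' @param min_corr minimum normalized cross-correlation peak for a column to
#'   contribute (default 0.3).
#' @param detrend_window odd window (frames) of a running-median detrend
#'   applied to the cumulative shifts, or `NULL` to disable. Frame-to-frame
#'   estimation noise accumulates along the chain as a slow random walk that
#'   would bend the volume; per-volume offsets and per-B-scan jitter are
#'   (near-)periodic at the interleaving period and survive the detrend.
#' @return numeric vector of corrections, one dz per frame (frame 1 is 0
#'   before detrending); applying each correction to its frame aligns the
#'   stack.
#' @export
axial_align_bscans <- function(frames, max_lag = 8L, min_corr = 0.3,
                               detrend_window = NULL, min_valid_frac = 0.25) {
  if (length(frames) < 2L) stop("need at least 2 frames")
  widths <- vapply(frames, ncol, integer(1))
  if (length(unique(widths)) != 1L) stop("frames have mismatched widths")
  shifts <- numeric(length(frames))
  prev <- frames[[1]]
  for (i in seq_along(frames)[-1]) {
    disp <- frame_axial_displacement(frames[[i]], prev, max_lag, min_corr,
                                     min_valid_frac)
    shifts[i] <- -disp
    aligned <- axis_shift(frames[[i]], 1, shifts[i])$data
    prev <- fill_na_mean(aligned)
  }
  if (!is.null(detrend_window) && detrend_window >= 3 &&
      length(shifts) >= detrend_window) {
    w <- detrend_window + (1 - detrend_window %% 2) # force odd
    k <- (w - 1) %/% 2
    # reflect-pad so the running median has full support at the stack ends
    padded <- c(rev(shifts[seq_len(k) + 1L]), shifts,
                rev(shifts[length(shifts) - seq_len(k)]))
    trend <- stats::runmed(padded, w)[k + seq_along(shifts)]
    shifts <- shifts - trend
  }
  shifts
}

# Mean per-column vertical displacement of frame F relative to frame P.
# Columns whose normalized cross-correlation peak is below `min_corr`, or
# which are (near-)constant, are excluded; a 3-point parabolic fit refines
# each column's peak to sub-pixel precision. When fewer than `min_valid_frac`
# of the columns pass, the frames share no usable structure (a handful of
# noise columns would otherwise dictate a large random shift) and 0 is
# returned.
frame_axial_displacement <- function(F, P, max_lag = 8L, min_corr = 0.3,
                                     min_valid_frac = 0.25) {
  F <- fill_na_mean(F)
  P <- fill_na_mean(P)
  nz <- nrow(F)
  nc <- ncol(F)
  lags <- -max_lag:max_lag
  Fc <- sweep(F, 2, colMeans(F))
  Pc <- sweep(P, 2, colMeans(P))
  scores <- matrix(-Inf, length(lags), nc)
  for (li in seq_along(lags)) {
    l <- lags[li]
    # F content displaced by +l relative to P: F[z] = P[z - l], so F rows
    # (1+l..nz) overlap P rows (1..nz-l)
    if (l >= 0) {
      fr <- (1 + l):nz
      pr <- 1:(nz - l)
    } else {
      fr <- 1:(nz + l)
      pr <- (1 - l):nz
    }
    num <- colSums(Pc[pr, , drop = FALSE] * Fc[fr, , drop = FALSE])
    den <- sqrt(colSums(Pc[pr, , drop = FALSE]^2) * colSums(Fc[fr, , drop = FALSE]^2))
    scores[li, ] <- ifelse(den > 0, num / den, -Inf)
  }
  best <- apply(scores, 2, which.max)
  peak <- scores[cbind(best, seq_len(nc))]
  valid <- is.finite(peak) & peak >= min_corr
  if (mean(valid) < min_valid_frac) return(0)
  disp <- numeric(nc)
  for (j in which(valid)) {
    bi <- best[j]
    l <- lags[bi]
    if (bi > 1 && bi < length(lags) &&
        is.finite(scores[bi - 1, j]) && is.finite(scores[bi + 1, j])) {
      y0 <- scores[bi - 1, j]; y1 <- scores[bi, j]; y2 <- scores[bi + 1, j]
      denom <- y0 - 2 * y1 + y2
      if (denom < 0) l <- l + 0.5 * (y0 - y2) / denom
    }
    disp[j] <- l
  }
  mean(disp[valid])
}

#' Apply a displacement record to a volume
#'
#' Applies the rigid XZ transform to every B-scan, then the en face XY
#' translation, then the per-B-scan axial shifts, all by linear interpolation.
#' The valid mask is updated so voxels sourced from outside the original grid
#' are invalid.
#'
#' @param vol an [oct_volume].
#' @param rec a [displacement_record] of corrections to apply.
#' @return corrected [oct_volume].
#' @export
apply_displacement <- function(vol, rec) {
  stopifnot(inherits(vol, "oct_volume"), inherits(rec, "displacement_record"))
  d <- dim(vol$data)
  ax <- rec$stage3_axial
  if (length(ax) == 0L) ax <- numeric(d[1])
  if (length(ax) != d[1]) stop("stage3 record length must equal n_bscans")
  if (max(abs(c(rec$stage1_xz[1:2], rec$stage2_xy, ax))) >= min(d)) {
    stop("shift exceeds volume extent")
  }
  mv <- move_volume(vol$data, vol_mask(vol),
                    xz = rec$stage1_xz, xy = rec$stage2_xy, axial = ax)
  keep_mask <- if (is.null(vol$valid_mask) && all(mv$mask)) NULL else mv$mask
  oct_volume(mv$data, pitch_um = vol$pitch_um, valid_mask = keep_mask,
             meta = vol$meta)
}

#' Mask-weighted average of an aligned batch
#'
#' Per-voxel mean over members whose valid mask is true; output voxels with no
#' contributor are zero and masked invalid. The per-voxel contributor count is
#' kept in `meta$contributors`.
#'
#' @param batch a [volume_series] (already aligned).
#' @return an [oct_volume].
#' @export
average_batch <- function(batch) {
  stopifnot(inherits(batch, "volume_series"))
  if (length(batch$volumes) == 0L) stop("empty batch")
  d <- dim(batch$volumes[[1]]$data)
  acc <- array(0, dim = d)
  cnt <- array(0L, dim = d)
  any_mask <- FALSE
  for (v in batch$volumes) {
    if (is.null(v$valid_mask)) {
      acc <- acc + v$data
      cnt <- cnt + 1L
    } else {
      any_mask <- TRUE
      acc <- acc + v$data * v$valid_mask
      cnt <- cnt + v$valid_mask
    }
  }
  out <- acc / pmax(cnt, 1L)
  mask <- if (any_mask) cnt >= 1L else NULL
  oct_volume(out, pitch_um = batch$volumes[[1]]$pitch_um, valid_mask = mask,
             meta = list(n_members = length(batch$volumes), contributors = cnt))
}

#' Three-stage registration of a volume batch
#'
#' Stages run in order, each on the output of the previous: (1) rigid XZ
#' registration of side projections against the batch's first volume, (2)
#' sub-pixel en face XY phase correlation of standard-deviation projections,
#' (3) per-B-scan axial alignment along the reorganized B-scan stack. Each
#' stage's estimates are applied before the next stage and logged.
#'
#' @param batch a [volume_series] of size >= 2.
#' @param cfg a [run_config()].
#' @return list with `series` (aligned volumes) and `records` (one
#'   [displacement_record] of applied corrections per volume).
#' @export
register_batch <- function(batch, cfg = run_config()) {
  stopifnot(inherits(batch, "volume_series"))
  n_v <- length(batch$volumes)
  if (n_v < 2L) stop("batch size must be >= 2")
  d <- dim(batch$volumes[[1]]$data)
  vols <- batch$volumes
  recs <- lapply(seq_len(n_v), function(i) {
    displacement_record(stage3_axial = numeric(d[1]))
  })

  # stage 1: rigid XZ on side projections, reference = first volume
  ref_sp <- side_projection(vols[[1]], cfg$central_bscans)
  for (v in seq_len(n_v)[-1]) {
    est <- rigid_register_xz(side_projection(vols[[v]], cfg$central_bscans),
                             ref_sp, cfg$rot_search_deg, cfg$rot_step_deg)
    recs[[v]]$stage1_xz <- est
    vols[[v]] <- apply_displacement(vols[[v]], displacement_record(
      stage1_xz = est, stage3_axial = numeric(d[1])
    ))
    octra_log("stage1 vol %d: dx=%.3f dz=%.3f rot=%.3f deg",
              v, est[1], est[2], est[3])
  }

  # stage 2: sub-pixel en face XY phase correlation, reference = first volume
  ref_ef <- fill_na_mean(enface_stddev_projection(vols[[1]], cfg$enface_depth_range))
  for (v in seq_len(n_v)[-1]) {
    ef <- fill_na_mean(enface_stddev_projection(vols[[v]], cfg$enface_depth_range))
    est <- if (ncc_score(gauss_smooth(ef, 1.5), gauss_smooth(ref_ef, 1.5)) < 0.35) {
      octra_log("stage2 vol %d: projections share no usable structure, skipped", v)
      c(dx = 0, dy = 0)
    } else {
      sh <- phase_correlation_shift(ef, ref_ef) # (d_b, d_x)
      c(dx = unname(sh[2]), dy = unname(sh[1]))
    }
    recs[[v]]$stage2_xy <- est
    vols[[v]] <- apply_displacement(vols[[v]], displacement_record(
      stage2_xy = est, stage3_axial = numeric(d[1])
    ))
    octra_log("stage2 vol %d: dx=%.3f dy=%.3f", v, est[1], est[2])
  }

  # stage 3: axial alignment along the reorganized B-scan stack; invalid
  # border voxels are mean-filled for estimation so they carry no edges
  ro <- reorganize_bscans(volume_series(vols, batch$acquisition_index))
  frames <- lapply(seq_len(nrow(ro$index_map)), function(i) {
    v <- ro$index_map$volume[i]
    b <- ro$index_map$bscan[i]
    fr <- vols[[v]]$data[b, , ]
    if (!is.null(vols[[v]]$valid_mask)) {
      fr[!vols[[v]]$valid_mask[b, , ]] <- NA_real_
      fr <- fill_na_mean(fr)
    }
    fr
  })
  shifts <- axial_align_bscans(frames, cfg$stage3_max_lag, cfg$stage3_min_corr,
                               detrend_window = 8L * n_v + 1L)
  for (v in seq_len(n_v)) {
    fs <- ro$index_map$frame[ro$index_map$volume == v]
    dz <- shifts[fs][order(ro$index_map$bscan[ro$index_map$volume == v])]
    recs[[v]]$stage3_axial <- dz
    if (any(dz != 0)) {
      vols[[v]] <- apply_displacement(vols[[v]], displacement_record(
        stage3_axial = dz
      ))
    }
    octra_log("stage3 vol %d: mean dz=%.3f max |dz|=%.3f",
              v, mean(dz), max(abs(dz)))
  }

  list(series = volume_series(vols, batch$acquisition_index), records = recs)
}

# Round sizes of the hierarchical scheme: ceiling division by the batch size
# until one volume remains.
hierarchy_round_sizes <- function(n, batch_size) {
  sizes <- n
  while (n > 1L) {
    n <- as.integer(ceiling(n / batch_size))
    sizes <- c(sizes, n)
  }
  sizes
}

#' Hierarchical registration and averaging of a volume series
#'
#' Rounds of (partition into consecutive batches, register each batch, average
#' each batch) repeat until a single volume remains. A final partial batch of
#' size >= 2 is processed as its own batch; a leftover singleton passes
#' through unmodified. A length-1 series is returned as-is.
#'
#' @param series a [volume_series].
#' @param cfg a [run_config()].
#' @param register run the three registration stages per batch (set `FALSE`
#'   for pre-aligned data).
#' @return list with `volume` (final [oct_volume]) and `trail` (data frame
#'   audit: round, batch, volume-within-batch, stage estimates).
#' @export
hierarchical_average <- function(series, cfg = run_config(), register = TRUE) {
  stopifnot(inherits(series, "volume_series"))
  current <- series$volumes
  trail <- list()
  round_i <- 0L
  while (length(current) > 1L) {
    round_i <- round_i + 1L
    n <- length(current)
    groups <- split(seq_len(n), ceiling(seq_len(n) / cfg$batch_size))
    octra_log("round %d: %d volumes -> %d batches", round_i, n, length(groups))
    nxt <- vector("list", length(groups))
    for (g in seq_along(groups)) {
      idx <- groups[[g]]
      if (length(idx) == 1L) {
        nxt[[g]] <- current[[idx]]
        next
      }
      batch <- volume_series(current[idx])
      if (register) {
        reg <- register_batch(batch, cfg)
        batch <- reg$series
        for (v in seq_along(idx)) {
          r <- reg$records[[v]]
          trail[[length(trail) + 1L]] <- data.frame(
            round = round_i, batch = g, member = v,
            dx = r$stage1_xz[1], dz = r$stage1_xz[2], rot = r$stage1_xz[3],
            dx2 = r$stage2_xy[1], dy2 = r$stage2_xy[2],
            dz3_mean = mean(r$stage3_axial), dz3_max = max(abs(r$stage3_axial))
          )
        }
      }
      nxt[[g]] <- average_batch(batch)
    }
    current <- nxt
  }
  trail <- if (length(trail)) do.call(rbind, trail) else data.frame()
  list(volume = current[[1]], trail = trail)
}
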