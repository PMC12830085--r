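# Semi-automated GCC segmentation: seeded extrema tracing on the vertical
# derivative of enhanced B-scans, surface growing across frames, and
# voxel-wise thickness maps.

#' Pair of retinal boundary surfaces and the derived thickness map
#'
#' Depths (voxels, sub-pixel allowed) of the anterior RNFL and posterior IPL
#' boundaries per `(b, x)`, plus the GCC thickness map
#' `(ipl_z - rnfl_z) * axial pitch`.
#'
#' @param rnfl_z,ipl_z numeric `(b, x)` matrices of boundary depths; `ipl_z`
#'   must exceed `rnfl_z` everywhere.
#' @param axial_pitch_um axial voxel pitch in micrometres.
#' @return object of class `layer_surface_pair` with `thickness_um`.
#' @export
layer_surface_pair <- function(rnfl_z, ipl_z, axial_pitch_um = 1) {
  if (!identical(dim(rnfl_z), dim(ipl_z))) stop("surfaces must share one grid")
  if (any(!is.finite(rnfl_z)) || any(!is.finite(ipl_z))) {
    stop("surface depths must be finite")
  }
  if (any(ipl_z <= rnfl_z)) {
    stop("posterior IPL boundary must lie below the anterior RNFL boundary everywhere")
  }
  structure(list(rnfl_z = rnfl_z, ipl_z = ipl_z,
                 thickness_um = (ipl_z - rnfl_z) * axial_pitch_um,
                 axial_pitch_um = axial_pitch_um),
            class = "layer_surface_pair")
}

#' @export
print.layer_surface_pair <- function(x, ...) {
  cat(sprintf("<layer_surface_pair> %d x %d, mean GCC thickness %.1f um\n",
              nrow(x$rnfl_z), ncol(x$rnfl_z), mean(x$thickness_um)))
  invisible(x)
}

#' Preprocess a B-scan for boundary tracing
#'
#' Enhancement is Gaussian smoothing plus min-max normalization to `[0, 1]`;
#' the vertical derivative is the forward difference along depth of the
#' enhanced image (last row zero-padded).
#'
#' @param bscan `(z, x)` matrix.
#' @param sigma Gaussian smoothing scale in px (default 1).
#' @return list with `enhanced` and `vertical_derivative`.
#' @export
preprocess_bscan <- function(bscan, sigma = 1) {
  sm <- if (sigma > 0 && min(dim(bscan)) > 2 * ceiling(3 * sigma) + 1) {
    EBImage::gblur(bscan, sigma = sigma, boundary = "replicate")
  } else {
    bscan
  }
  rng <- range(sm)
  enh <- if (diff(rng) > 0) (sm - rng[1]) / diff(rng) else sm * 0
  dv <- rbind(enh[-1, , drop = FALSE] - enh[-nrow(enh), , drop = FALSE],
              rep(0, ncol(enh)))
  list(enhanced = enh, vertical_derivative = dv)
}

#' Snap user marks to the strongest derivative extrema on one A-line
#'
#' The user marks an intensity peak (anterior RNFL) and a valley (posterior
#' IPL boundary) on a single A-line of the central B-scan; each mark is
#' snapped to the strongest local extremum of the vertical derivative within
#' `+-search` pixels.
#'
#' @param bscan `(z, x)` matrix.
#' @param aline_x A-line (column) index.
#' @param peak_z,valley_z user marks (depth px), `peak_z < valley_z`.
#' @param search axial search half-width in px (default 2).
#' @return list of seeds `peak = c(x, z)`, `valley = c(x, z)`.
#' @export
seed_boundaries <- function(bscan, aline_x, peak_z, valley_z, search = 2L) {
  nz <- nrow(bscan)
  if (aline_x < 1 || aline_x > ncol(bscan)) stop("A-line outside the B-scan")
  if (peak_z >= valley_z) stop("peak mark must lie above the valley mark")
  if (peak_z < 1 || valley_z > nz) stop("marks outside the depth range")
  dv <- preprocess_bscan(bscan)$vertical_derivative[, aline_x]
  snap <- function(z0, polarity) {
    win <- max(1, round(z0) - search):min(nz, round(z0) + search)
    if (polarity > 0) win[which.max(dv[win])] else win[which.min(dv[win])]
  }
  list(peak = c(x = aline_x, z = snap(peak_z, 1)),
       valley = c(x = aline_x, z = snap(valley_z, -1)))
}

#' Trace a boundary curve across a B-scan from a seed
#'
#' Marches outward from the seed column in both directions; each column's
#' boundary is the argmax (peak polarity) or argmin (valley polarity) of the
#' vertical derivative within `+-search` px of the neighbouring column's
#' boundary. Columns whose chosen extremum is weak relative to the seed
#' extremum are flagged as tracking losses. The curve is median-smoothed.
#'
#' @param bscan_derivative vertical-derivative `(z, x)` matrix (from
#'   [preprocess_bscan()]).
#' @param seed `c(x =, z =)` seed point.
#' @param polarity `"peak"` or `"valley"`.
#' @param search axial search half-width (default 2).
#' @param smooth median filter width in columns (default 5, odd).
#' @param lost_frac extremum magnitude below this fraction of the seed's
#'   magnitude flags a tracking loss (default 0.25).
#' @return list with `z` (numeric boundary per column) and `lost` (logical).
#' @export
trace_boundary <- function(bscan_derivative, seed, polarity = c("peak", "valley"),
                           search = 2L, smooth = 5L, lost_frac = 0.25) {
  polarity <- match.arg(polarity)
  sgn <- if (polarity == "peak") 1 else -1
  dv <- bscan_derivative * sgn # peaks everywhere
  nz <- nrow(dv)
  nc <- ncol(dv)
  x0 <- as.integer(seed["x"])
  if (x0 < 1 || x0 > nc) stop("seed column outside the B-scan")
  z <- numeric(nc)
  lost <- logical(nc)
  z[x0] <- seed["z"]
  ref_mag <- dv[round(seed["z"]), x0]
  step <- function(z_prev, x) {
    win <- max(1, round(z_prev) - search):min(nz, round(z_prev) + search)
    zi <- win[which.max(dv[win, x])]
    list(z = zi, lost = dv[zi, x] < lost_frac * ref_mag)
  }
  if (x0 < nc) {
    for (x in (x0 + 1):nc) {
      s <- step(z[x - 1], x)
      z[x] <- s$z
      lost[x] <- s$lost
    }
  }
  if (x0 > 1) {
    for (x in (x0 - 1):1) {
      s <- step(z[x + 1], x)
      z[x] <- s$z
      lost[x] <- s$lost
    }
  }
  if (any(z < 1 | z > nz)) stop("boundary driven out of the depth range")
  if (smooth > 1 && nc >= smooth) z <- stats::runmed(z, smooth, endrule = "median")
  list(z = as.numeric(z), lost = lost)
}

#' Grow boundary surfaces through a volume from central-B-scan seed curves
#'
#' Frames are processed outward from the central B-scan in both directions;
#' in each frame, every column's search window is centred on the previous
#' frame's boundary, so each boundary guides the next slice. Fails with a
#' diagnostic when more than `max_lost_frac` of columns lose track in any
#' frame.
#'
#' @param vol an [oct_volume].
#' @param aline_x,peak_z,valley_z central B-scan seed marks (see
#'   [seed_boundaries()]).
#' @param search axial search half-width (default 2).
#' @param smooth median filter width (default 5).
#' @param max_lost_frac abort threshold on the per-frame lost-column fraction
#'   (default 0.2).
#' @return a [layer_surface_pair] on the `(b, x)` grid.
#' @export
grow_surface <- function(vol, aline_x, peak_z, valley_z, search = 2L,
                         smooth = 5L, max_lost_frac = 0.2) {
  stopifnot(inherits(vol, "oct_volume"))
  d <- dim(vol$data)
  b0 <- d[1] %/% 2 + 1L
  central <- vol$data[b0, , ]
  seeds <- seed_boundaries(central, aline_x, peak_z, valley_z, search)
  rnfl <- matrix(NA_real_, d[1], d[3])
  ipl <- matrix(NA_real_, d[1], d[3])
  trace_frame <- function(bscan, guide_rnfl, guide_ipl) {
    dv <- preprocess_bscan(bscan)$vertical_derivative
    nz <- nrow(dv)
    pick <- function(guide, sgn) {
      z <- numeric(d[3])
      lost <- logical(d[3])
      for (x in seq_len(d[3])) {
        win <- max(1, round(guide[x]) - search):min(nz, round(guide[x]) + search)
        vals <- dv[win, x] * sgn
        zi <- win[which.max(vals)]
        z[x] <- zi
        lost[x] <- max(vals) <= 0
      }
      if (smooth > 1 && d[3] >= smooth) z <- stats::runmed(z, smooth, endrule = "median")
      list(z = z, lost = lost)
    }
    pr <- pick(guide_rnfl, 1)
    pv <- pick(guide_ipl, -1)
    frac <- max(mean(pr$lost), mean(pv$lost))
    if (frac > max_lost_frac) {
      stop(sprintf("surface growing lost track in %.0f%% of columns", 100 * frac))
    }
    list(rnfl = pr$z, ipl = pv$z)
  }
  dv0 <- preprocess_bscan(central)$vertical_derivative
  tr_r <- trace_boundary(dv0, seeds$peak, "peak", search, smooth)
  tr_v <- trace_boundary(dv0, seeds$valley, "valley", search, smooth)
  rnfl[b0, ] <- tr_r$z
  ipl[b0, ] <- tr_v$z
  for (dir in c(1L, -1L)) {
    guide_r <- rnfl[b0, ]
    guide_v <- ipl[b0, ]
    b <- b0 + dir
    while (b >= 1L && b <= d[1]) {
      fr <- trace_frame(vol$data[b, , ], guide_r, guide_v)
      rnfl[b, ] <- fr$rnfl
      ipl[b, ] <- fr$ipl
      guide_r <- fr$rnfl
      guide_v <- fr$ipl
      b <- b + dir
    }
  }
  layer_surface_pair(rnfl, ipl, axial_pitch_um = vol$pitch_um[2])
}
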