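# Soma detection and longitudinal quantification. The detector is an
# automated surrogate for manual z-stack counting, enforcing the same
# criteria: homogeneous hyperreflectivity (percentile threshold), round
# soma-like in-plane shape, and visibility across at least three consecutive
# depth frames.

# 6-connected 3-D component labelling by breadth-first frontier expansion.
label_components_3d <- function(mask) {
  d <- dim(mask)
  n <- prod(d)
  lab <- integer(n)
  fg <- which(mask)
  next_lab <- 0L
  nb_off <- function(idx) {
    # neighbours of linear indices in (b, z, x) order with boundary checks
    co <- arrayInd(idx, d)
    out <- integer(0)
    for (ax in 1:3) {
      for (s in c(-1L, 1L)) {
        co2 <- co
        co2[, ax] <- co2[, ax] + s
        ok <- co2[, ax] >= 1L & co2[, ax] <= d[ax]
        if (any(ok)) {
          out <- c(out, co2[ok, 1] + (co2[ok, 2] - 1L) * d[1] +
                     (co2[ok, 3] - 1L) * d[1] * d[2])
        }
      }
    }
    unique(out)
  }
  for (seed in fg) {
    if (lab[seed] != 0L) next
    next_lab <- next_lab + 1L
    lab[seed] <- next_lab
    frontier <- seed
    while (length(frontier)) {
      nb <- nb_off(frontier)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- next_lab
      frontier <- nb
    }
  }
  array(lab, dim = d)
}

#' Detect somas in an averaged volume
#'
#' Thresholds the layer band at an intensity percentile, labels 3-D connected
#' components, and keeps components that satisfy the counting criteria:
#' visible across at least `persistence_frames` consecutive depth frames,
#' in-plane equivalent diameter within `diameter_um`, and in-plane roundness
#' (minor/major axis ratio) of at least `min_roundness`. Meant for averaged
#' volumes: single-volume speckle defeats detection by design.
#'
#' @param vol an averaged [oct_volume].
#' @param band inclusive depth range `c(z_lo, z_hi)` of the cell layer.
#' @param percentile intensity percentile (within the band) used as the
#'   hyperreflectivity threshold (default 90).
#' @param diameter_um admissible equivalent-diameter range (default 5-10, the
#'   mouse RGC soma range).
#' @param min_roundness minimum in-plane minor/major axis ratio (default 0.6).
#' @param persistence_frames minimum consecutive depth frames (default 3).
#' @return data frame of cell records: `b, z, x` (centroid), `z_extent`
#'   (frames), `diameter_um`, `roundness`, `mean_intensity`.
#' @export
detect_somas <- function(vol, band, percentile = 90, diameter_um = c(5, 10),
                         min_roundness = 0.6, persistence_frames = 3L) {
  stopifnot(inherits(vol, "oct_volume"))
  d <- dim(vol$data)
  if (band[1] < 1 || band[2] > d[2] || band[1] >= band[2]) {
    stop("empty or invalid layer band")
  }
  slab <- vol$data[, band[1]:band[2], , drop = FALSE]
  thr <- stats::quantile(slab, percentile / 100, names = FALSE)
  lab <- label_components_3d(slab >= thr)
  k <- max(lab)
  if (k == 0L) {
    return(data.frame(b = numeric(0), z = numeric(0), x = numeric(0),
                      z_extent = integer(0), diameter_um = numeric(0),
                      roundness = numeric(0), mean_intensity = numeric(0)))
  }
  pb <- vol$pitch_um[1]
  px <- vol$pitch_um[3]
  recs <- vector("list", k)
  idx_all <- which(lab > 0)
  co_all <- arrayInd(idx_all, dim(lab))
  lab_v <- lab[idx_all]
  for (ci in seq_len(k)) {
    co <- co_all[lab_v == ci, , drop = FALSE]
    zext <- diff(range(co[, 2])) + 1L
    if (zext < persistence_frames) next
    # in-plane footprint (en face projection of the component); the
    # half-pixel boundary correction compensates the systematic area loss of
    # a thresholded, digitized disc (its sampled footprint stops about half a
    # pixel inside the true rim)
    plane <- unique(co[, c(1, 3), drop = FALSE])
    area_um2 <- nrow(plane) * pb * px
    eqd <- 2 * sqrt(area_um2 / pi) + (pb + px) / 2
    if (eqd < diameter_um[1] || eqd > diameter_um[2]) next
    roundness <- if (nrow(plane) >= 3) {
      cv <- stats::cov(cbind(plane[, 1] * pb, plane[, 2] * px))
      ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
      if (ev[1] <= 0) 1 else sqrt(max(ev[2], 0) / ev[1])
    } else 1
    if (roundness < min_roundness) next
    vox <- slab[co]
    recs[[ci]] <- data.frame(
      b = mean(co[, 1]), z = mean(co[, 2]) + band[1] - 1, x = mean(co[, 3]),
      z_extent = zext, diameter_um = eqd, roundness = roundness,
      mean_intensity = mean(vox)
    )
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (!length(recs)) {
    return(data.frame(b = numeric(0), z = numeric(0), x = numeric(0),
                      z_extent = integer(0), diameter_um = numeric(0),
                      roundness = numeric(0), mean_intensity = numeric(0)))
  }
  do.call(rbind, recs)
}

#' Match detected cells against ground-truth centroids
#'
#' Greedy nearest-neighbour matching in the en face plane with a match radius
#' of one cell radius; returns precision and recall.
#'
#' @param detected data frame from [detect_somas()].
#' @param truth_cells ground-truth data frame with `b, x, radius_um`.
#' @param pitch_um voxel pitch `c(b, z, x)`.
#' @return list with `precision`, `recall`, `n_matched`.
#' @export
match_somas <- function(detected, truth_cells, pitch_um) {
  if (nrow(truth_cells) == 0L) {
    return(list(precision = if (nrow(detected)) 0 else 1, recall = 1, n_matched = 0L))
  }
  if (nrow(detected) == 0L) {
    return(list(precision = 1, recall = 0, n_matched = 0L))
  }
  used <- logical(nrow(truth_cells))
  matched <- 0L
  for (i in seq_len(nrow(detected))) {
    db <- (detected$b[i] - truth_cells$b) * pitch_um[1]
    dx <- (detected$x[i] - truth_cells$x) * pitch_um[3]
    dist <- sqrt(db^2 + dx^2)
    ok <- which(!used & dist <= truth_cells$radius_um)
    if (length(ok)) {
      used[ok[which.min(dist[ok])]] <- TRUE
      matched <- matched + 1L
    }
  }
  list(precision = matched / nrow(detected),
       recall = matched / nrow(truth_cells),
       n_matched = matched)
}

#' Cell count to planar density
#'
#' @param count cell count.
#' @param fov_um field of view `c(width, height)` in micrometres.
#' @return object of class `count_summary`: `count`, `area_mm2`,
#'   `density_per_mm2`.
#' @export
count_density <- function(count, fov_um = c(310, 310)) {
  if (any(fov_um <= 0)) stop("field of view must be positive")
  area_mm2 <- prod(fov_um) / 1e6
  structure(list(count = count, area_mm2 = area_mm2,
                 density_per_mm2 = count / area_mm2),
            class = "count_summary")
}

#' @export
print.count_summary <- function(x, ...) {
  cat(sprintf("<count_summary> %g cells over %.4f mm2 = %.0f cells/mm2\n",
              x$count, x$area_mm2, x$density_per_mm2))
  invisible(x)
}

#' Percent change from baseline
#'
#' `(baseline - value) / baseline * 100`; positive for a reduction. Summaries
#' report it rounded to the nearest integer percent.
#'
#' @param baseline,value scalars, `baseline != 0`.
#' @return percent change (unrounded).
#' @export
percent_change <- function(baseline, value) {
  if (baseline == 0) stop("baseline must be nonzero")
  (baseline - value) / baseline * 100
}

#' Concordance (detection rate) between two counts
#'
#' `count_a / count_b * 100`; summaries report it rounded to the nearest
#' integer percent.
#'
#' @param count_a,count_b counts, `count_b > 0`.
#' @return percent (unrounded).
#' @export
concordance <- function(count_a, count_b) {
  if (count_b <= 0) stop("denominator count must be positive")
  count_a / count_b * 100
}

#' Longitudinal summary table
#'
#' Per timepoint: mean cell count across patches, density, mean GCC thickness,
#' and integer percent changes versus baseline (the first timepoint).
#'
#' @param timepoints list of entries, each a list with `timepoint`, `counts`
#'   (vector, one per patch), optional `thickness_um` (vector or matrix), and
#'   optional `fov_um` (defaults to 310 x 310).
#' @return data frame with columns `timepoint, mean_count, density_per_mm2,
#'   mean_thickness_um, pct_loss_count, pct_loss_thickness`.
#' @export
longitudinal_summary <- function(timepoints) {
  if (!length(timepoints)) stop("missing baseline timepoint")
  rows <- lapply(timepoints, function(tp) {
    fov <- if (is.null(tp$fov_um)) c(310, 310) else tp$fov_um
    mc <- mean(tp$counts)
    th <- if (is.null(tp$thickness_um)) NA_real_ else mean(tp$thickness_um)
    data.frame(timepoint = tp$timepoint, mean_count = mc,
               density_per_mm2 = count_density(mc, fov)$density_per_mm2,
               mean_thickness_um = th)
  })
  out <- do.call(rbind, rows)
  out$pct_loss_count <- round(percent_change(out$mean_count[1], out$mean_count))
  out$pct_loss_thickness <- if (is.na(out$mean_thickness_um[1])) {
    NA_real_
  } else {
    round(percent_change(out$mean_thickness_um[1], out$mean_thickness_um))
  }
  out
}
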