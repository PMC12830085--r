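#' OCT intensity volume
#'
#' Container for a single 3-D OCT intensity volume. The data array is indexed
#' `(b, z, x)`: B-scan index, depth, A-scan index. Intensities must be finite
#' and non-negative. An optional `valid_mask` of identical shape marks voxels
#' that carry real signal; voxels interpolated in from outside the original
#' grid during motion or registration are flagged invalid so that averaging
#' never ingests fabricated intensities.
#'
#' @param data 3-D numeric array indexed `(b, z, x)`, finite and `>= 0`.
#' @param pitch_um voxel pitch in micrometres, `c(lateral_b, axial_z,
#'   lateral_x)`. Defaults to the native grid of a 310 um field sampled by 512
#'   A-scans laterally (310/512 ~ 0.605 um) and 1 um axially.
#' @param valid_mask optional logical array, same shape as `data`.
#' @param meta free-form named list of provenance.
#' @return An object of class `oct_volume`.
#' @examples
#' v <- oct_volume(array(1, dim = c(4, 8, 8)))
#' dim(v$data)
#' @export
oct_volume <- function(data,
                       pitch_um = c(310 / 512, 1, 310 / 512),
                       valid_mask = NULL,
                       meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3-D array indexed (b, z, x)")
  }
  storage.mode(data) <- "double"
  if (anyNA(data) || any(!is.finite(data))) {
    stop("intensities must all be finite")
  }
  if (any(data < 0)) stop("intensities must be non-negative")
  pitch_um <- as.numeric(pitch_um)
  if (length(pitch_um) != 3L || any(!is.finite(pitch_um)) || any(pitch_um <= 0)) {
    stop("`pitch_um` must be 3 positive values (lateral_b, axial_z, lateral_x)")
  }
  if (!is.null(valid_mask)) {
    if (!identical(dim(valid_mask), dim(data))) {
      stop("`valid_mask` must have the same shape as `data`")
    }
    storage.mode(valid_mask) <- "logical"
    if (anyNA(valid_mask)) stop("`valid_mask` must not contain NA")
  }
  structure(
    list(data = data, pitch_um = pitch_um, valid_mask = valid_mask, meta = meta),
    class = "oct_volume"
  )
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<oct_volume> %d B-scans x %d depth x %d A-scans, pitch (%.3g, %.3g, %.3g) um\n",
    d[1], d[2], d[3], x$pitch_um[1], x$pitch_um[2], x$pitch_um[3]
  ))
  if (!is.null(x$valid_mask)) {
    cat(sprintf("  valid voxels: %.1f%%\n", 100 * mean(x$valid_mask)))
  }
  invisible(x)
}

#' @export
dim.oct_volume <- function(x) dim(x$data)

#' Valid-voxel mask of a volume
#'
#' Returns the volume's `valid_mask`, or an all-`TRUE` array when none is set.
#'
#' @param vol an [oct_volume].
#' @return logical array, same shape as `vol$data`.
#' @export
vol_mask <- function(vol) {
  if (is.null(vol$valid_mask)) {
    array(TRUE, dim = dim(vol$data))
  } else {
    vol$valid_mask
  }
}

#' Ordered series of OCT volumes
#'
#' All member volumes must share shape and pitch. The series is the unit of
#' registration and averaging.
#'
#' @param volumes list of [oct_volume] objects, length >= 1.
#' @param acquisition_index integer acquisition order, one per volume.
#' @return An object of class `volume_series`.
#' @export
volume_series <- function(volumes, acquisition_index = seq_along(volumes)) {
  if (!is.list(volumes) || length(volumes) < 1L) {
    stop("`volumes` must be a non-empty list of oct_volume objects")
  }
  if (!all(vapply(volumes, inherits, logical(1), "oct_volume"))) {
    stop("all members must be oct_volume objects")
  }
  d0 <- dim(volumes[[1]]$data)
  p0 <- volumes[[1]]$pitch_um
  for (v in volumes) {
    if (!identical(dim(v$data), d0)) stop("all volumes must share one shape")
    if (!isTRUE(all.equal(v$pitch_um, p0))) stop("all volumes must share one pitch")
  }
  acquisition_index <- as.integer(acquisition_index)
  if (length(acquisition_index) != length(volumes)) {
    stop("`acquisition_index` must have one entry per volume")
  }
  structure(
    list(volumes = volumes, acquisition_index = acquisition_index),
    class = "volume_series"
  )
}

#' @export
length.volume_series <- function(x) length(x$volumes)

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$volumes[[1]]$data)
  cat(sprintf(
    "<volume_series> %d volumes of %d x %d x %d (b, z, x)\n",
    length(x$volumes), d[1], d[2], d[3]
  ))
  invisible(x)
}

#' Per-volume displacement record
#'
#' Holds the motion estimates (or applied ground-truth motions) of the three
#' registration stages for one volume. All entries are signed voxel shifts;
#' positive values move content towards larger indices. `stage2_xy` is the en
#' face translation `(dx, dy)` where `dx` is along the A-scan (x) axis and
#' `dy` along the B-scan (b) axis.
#'
#' @param stage1_xz numeric `c(dx, dz, rot_deg)`: rigid B-scan-plane transform.
#' @param stage2_xy numeric `c(dx, dy)`: sub-pixel en face translation.
#' @param stage3_axial numeric vector, one axial shift (dz) per B-scan.
#' @return An object of class `displacement_record`.
#' @export
displacement_record <- function(stage1_xz = c(dx = 0, dz = 0, rot_deg = 0),
                                stage2_xy = c(dx = 0, dy = 0),
                                stage3_axial = numeric(0)) {
  stage1_xz <- setNames(as.numeric(stage1_xz), c("dx", "dz", "rot_deg"))
  stage2_xy <- setNames(as.numeric(stage2_xy), c("dx", "dy"))
  stage3_axial <- as.numeric(stage3_axial)
  if (any(!is.finite(c(stage1_xz, stage2_xy, stage3_axial)))) {
    stop("displacement entries must be finite")
  }
  structure(
    list(stage1_xz = stage1_xz, stage2_xy = stage2_xy, stage3_axial = stage3_axial),
    class = "displacement_record"
  )
}

#' @export
print.displacement_record <- function(x, ...) {
  cat(sprintf(
    "<displacement_record> xz=(%.3f, %.3f, %.3f deg) xy=(%.3f, %.3f) axial[n=%d] mean=%.3f\n",
    x$stage1_xz[1], x$stage1_xz[2], x$stage1_xz[3],
    x$stage2_xy[1], x$stage2_xy[2],
    length(x$stage3_axial),
    if (length(x$stage3_axial)) mean(x$stage3_axial) else 0
  ))
  invisible(x)
}
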