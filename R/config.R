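#' Pipeline run configuration
#'
#' Bundles the tunable parameters shared across the registration, metrics and
#' quantification stages.
#'
#' @param batch_size volumes per averaging batch (default 6).
#' @param central_bscans B-scans used for the stage-1 side projection
#'   (default 60).
#' @param enface_depth_range inclusive depth range `c(z_lo, z_hi)` for the en
#'   face standard-deviation projection, or `NULL` for the full depth.
#' @param patch_size patch edge in pixels for Tenengrad/contrast maps
#'   (default 20).
#' @param axial_search_px half-width of the axial search window used by the
#'   boundary tracer (default 2).
#' @param persistence_frames minimum number of consecutive depth frames a
#'   detected soma must span (default 3).
#' @param fov_um lateral field of view `c(width, height)` in micrometres
#'   (default 310 x 310).
#' @param deg_to_um retinal conversion factor, micrometres per degree of
#'   visual angle (default 36).
#' @param rot_search_deg half-range of the stage-1 rotation scan (default 2).
#' @param rot_step_deg rotation scan step (default 0.1).
#' @param stage3_max_lag half-width in pixels of the per-column axial
#'   cross-correlation search (default 8).
#' @param stage3_min_corr minimum normalized cross-correlation peak for a
#'   column to contribute to a frame's axial shift (default 0.3).
#' @param seed integer seed for stages that draw random numbers.
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(batch_size = 6L,
                       central_bscans = 60L,
                       enface_depth_range = NULL,
                       patch_size = 20L,
                       axial_search_px = 2L,
                       persistence_frames = 3L,
                       fov_um = c(310, 310),
                       deg_to_um = 36,
                       rot_search_deg = 2,
                       rot_step_deg = 0.1,
                       stage3_max_lag = 8L,
                       stage3_min_corr = 0.3,
                       seed = 1L) {
  cfg <- list(
    batch_size = as.integer(batch_size),
    central_bscans = as.integer(central_bscans),
    enface_depth_range = if (is.null(enface_depth_range)) NULL else as.numeric(enface_depth_range),
    patch_size = as.integer(patch_size),
    axial_search_px = as.integer(axial_search_px),
    persistence_frames = as.integer(persistence_frames),
    fov_um = as.numeric(fov_um),
    deg_to_um = as.numeric(deg_to_um),
    rot_search_deg = as.numeric(rot_search_deg),
    rot_step_deg = as.numeric(rot_step_deg),
    stage3_max_lag = as.integer(stage3_max_lag),
    stage3_min_corr = as.numeric(stage3_min_corr),
    seed = as.integer(seed)
  )
  if (cfg$batch_size < 2L) stop("`batch_size` must be >= 2")
  if (cfg$patch_size < 2L) stop("`patch_size` must be >= 2")
  if (cfg$central_bscans < 1L) stop("`central_bscans` must be >= 1")
  if (!is.null(cfg$enface_depth_range)) {
    r <- cfg$enface_depth_range
    if (length(r) != 2L || r[1] < 1 || r[2] <= r[1]) {
      stop("`enface_depth_range` must be c(z_lo, z_hi) with 1 <= z_lo < z_hi")
    }
  }
  if (length(cfg$fov_um) != 2L || any(cfg$fov_um <= 0)) {
    stop("`fov_um` must be two positive lengths")
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys absent from the file keep their [run_config()] defaults.
#'
#' @param path YAML file as written by [write_run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' Write a run configuration to a YAML file
#'
#' @param cfg a [run_config()].
#' @param path destination file.
#' @return `invisible(path)`.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
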