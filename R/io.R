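# Volume I/O. Volumes travel as multi-page TIFFs: one 32-bit IEEE-float page
# per B-scan (rows = depth z, columns = A-scan x), optionally followed by the
# same number of 0/1 float pages encoding the valid mask. Page 1 carries a
# JSON ImageDescription tag with the pitch and layout so a written file is
# self-describing. Reading goes through tiff::readTIFF, which decodes float
# TIFFs exactly; the CRAN tiff package cannot *write* float samples (its
# 32-bit path stores unsigned integers and wraps values outside [0, 1]), so
# writing uses the minimal single-strip float writer below.

#' Read an OCT volume from a multi-page TIFF
#'
#' Pages map to the B-scan index in file order; page rows/columns map to
#' `(z, x)`. Files written by [write_volume()] restore pitch, metadata and the
#' valid mask from the embedded description tag; for foreign TIFFs the
#' `pitch_um` fallback is used.
#'
#' @param path TIFF file.
#' @param pitch_um fallback voxel pitch when the file carries none.
#' @return An [oct_volume].
#' @export
read_volume <- function(path, pitch_um = c(310 / 512, 1, 310 / 512)) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (length(pages) == 0L) stop("TIFF contains no pages: ", path)
  dims <- lapply(pages, dim)
  if (length(unique(lapply(dims, function(d) d[1:2]))) != 1L) {
    stop("TIFF pages have differing sizes (ragged pages): ", path)
  }
  if (any(vapply(dims, length, integer(1)) > 2L)) {
    # collapse multi-channel pages are not supported
    stop("TIFF pages must be single-channel grayscale: ", path)
  }
  desc <- attr(pages[[1]], "description")
  info <- NULL
  if (!is.null(desc) && nzchar(desc)) {
    info <- tryCatch(jsonlite::fromJSON(desc), error = function(e) NULL)
    if (!is.list(info) || is.null(info$octra)) info <- NULL
  }
  n_pages <- length(pages)
  has_mask <- isTRUE(info$has_mask)
  n_b <- if (!is.null(info$n_bscans)) as.integer(info$n_bscans) else n_pages
  if (has_mask && n_pages != 2L * n_b) stop("mask page count mismatch in ", path)
  if (!has_mask && n_pages != n_b) stop("page count mismatch in ", path)
  if (!is.null(info$pitch_um)) pitch_um <- as.numeric(info$pitch_um)
  scale <- if (!is.null(info$intensity_scale)) as.numeric(info$intensity_scale) else 1
  nz <- nrow(pages[[1]])
  nx <- ncol(pages[[1]])
  data <- array(0, dim = c(n_b, nz, nx))
  for (b in seq_len(n_b)) data[b, , ] <- pages[[b]] * scale
  mask <- NULL
  if (has_mask) {
    mask <- array(TRUE, dim = c(n_b, nz, nx))
    for (b in seq_len(n_b)) mask[b, , ] <- pages[[n_b + b]] > 0.5
  }
  oct_volume(data, pitch_um = pitch_um, valid_mask = mask,
             meta = list(source = path))
}

#' Write an OCT volume to a multi-page float TIFF
#'
#' One uncompressed 32-bit IEEE-float page per B-scan; the valid mask, when
#' present, is appended as a companion page set of 0/1 pages. Intensities are
#' divided by a power-of-two scale (recorded in the description tag) so that
#' stored samples lie in [0, 1]; because the scale is a power of two the
#' round trip is exact at float32 precision.
#'
#' @param vol an [oct_volume].
#' @param path destination file; the parent directory must exist.
#' @return `invisible(path)`.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "oct_volume"))
  if (!dir.exists(dirname(path))) stop("parent directory does not exist: ", dirname(path))
  d <- dim(vol$data)
  mx <- max(vol$data)
  scale <- if (mx > 1) 2^ceiling(log2(mx)) else 1
  pages <- lapply(seq_len(d[1]), function(b) vol$data[b, , ] / scale)
  if (!is.null(vol$valid_mask)) {
    pages <- c(pages, lapply(seq_len(d[1]), function(b) vol$valid_mask[b, , ] * 1))
  }
  desc <- jsonlite::toJSON(list(
    octra = 1L, n_bscans = d[1], has_mask = !is.null(vol$valid_mask),
    pitch_um = vol$pitch_um, intensity_scale = scale
  ), auto_unbox = TRUE, digits = NA)
  write_float_tiff(pages, path, description = as.character(desc))
  invisible(path)
}

# Minimal multi-page 32-bit IEEE-float TIFF writer (little-endian, one strip
# per page, no compression). Written because tiff::writeTIFF has no float
# sample format; files are read back with tiff::readTIFF.
write_float_tiff <- function(pages, path, description = "") {
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(x, size) writeBin(x, con, size = size, endian = "little")
  desc_nul <- c(charToRaw(description), as.raw(0)) # ASCII count includes NUL
  desc_raw <- if (length(desc_nul) %% 2L) c(desc_nul, as.raw(0)) else desc_nul
  # header
  writeBin(charToRaw("II"), con)
  w(42L, 2)
  offset <- 8L # running file offset after header
  first_ifd <- NA_integer_
  # layout per page: [strip data][description (page 1 only)][IFD]
  entry <- function(tag, type, count, value) c(tag, type, count, value)
  plan <- list()
  for (p in seq_along(pages)) {
    m <- pages[[p]]
    nbytes <- length(m) * 4L
    strip_off <- offset
    offset <- offset + nbytes
    desc_off <- 0L
    use_desc <- p == 1L && nchar(description) > 0L
    if (use_desc) {
      desc_off <- offset
      offset <- offset + length(desc_raw)
    }
    ifd_off <- offset
    n_entries <- 10L + as.integer(use_desc)
    offset <- offset + 2L + n_entries * 12L + 4L
    plan[[p]] <- list(m = m, strip_off = strip_off, desc_off = desc_off,
                      ifd_off = ifd_off, use_desc = use_desc, nbytes = nbytes)
    if (p == 1L) first_ifd <- ifd_off
  }
  w(as.integer(plan[[1]]$ifd_off), 4)
  TYPE_SHORT <- 3L; TYPE_LONG <- 4L; TYPE_ASCII <- 2L
  for (p in seq_along(plan)) {
    pl <- plan[[p]]
    # strip: row-major float32
    writeBin(as.numeric(t(pl$m)), con, size = 4, endian = "little")
    if (pl$use_desc) writeBin(desc_raw, con)
    ents <- list(
      entry(256L, TYPE_LONG, 1L, ncol(pl$m)),            # ImageWidth
      entry(257L, TYPE_LONG, 1L, nrow(pl$m)),            # ImageLength
      entry(258L, TYPE_SHORT, 1L, 32L),                  # BitsPerSample
      entry(259L, TYPE_SHORT, 1L, 1L),                   # Compression: none
      entry(262L, TYPE_SHORT, 1L, 1L)                    # Photometric: BlackIsZero
    )
    if (pl$use_desc) {
      ents <- c(ents, list(entry(270L, TYPE_ASCII, length(desc_nul), pl$desc_off)))
    }
    ents <- c(ents, list(
      entry(273L, TYPE_LONG, 1L, pl$strip_off),          # StripOffsets
      entry(277L, TYPE_SHORT, 1L, 1L),                   # SamplesPerPixel
      entry(278L, TYPE_LONG, 1L, nrow(pl$m)),            # RowsPerStrip
      entry(279L, TYPE_LONG, 1L, pl$nbytes)              # StripByteCounts
    ))
    # SampleFormat must come after (tags ascending): 339
    ents <- c(ents, list(entry(339L, TYPE_SHORT, 1L, 3L)))
    ents <- ents[order(vapply(ents, `[`, numeric(1), 1L))]
    w(length(ents), 2)
    for (e in ents) {
      w(as.integer(e[1]), 2)
      w(as.integer(e[2]), 2)
      w(as.integer(e[3]), 4)
      if (e[2] == TYPE_SHORT) {
        w(as.integer(e[4]), 2)
        w(0L, 2)
      } else {
        w(as.integer(e[4]), 4)
      }
    }
    next_ifd <- if (p < length(plan)) plan[[p + 1L]]$ifd_off else 0L
    w(as.integer(next_ifd), 4)
  }
  invisible(path)
}

#' Write a volume series to a directory of TIFF volumes
#'
#' Files are named `vol_001.tiff`, `vol_002.tiff`, ... in acquisition order.
#'
#' @param series a [volume_series].
#' @param dir destination directory (created if missing).
#' @return invisible character vector of file paths.
#' @export
write_series <- function(series, dir) {
  stopifnot(inherits(series, "volume_series"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("vol_%03d.tiff", seq_along(series$volumes)))
  for (i in seq_along(series$volumes)) write_volume(series$volumes[[i]], paths[i])
  invisible(paths)
}

#' Read a directory of TIFF volumes as a series
#'
#' @param dir directory containing TIFF volumes (read in lexical order).
#' @param pitch_um fallback pitch passed to [read_volume()].
#' @return A [volume_series].
#' @export
read_series <- function(dir, pitch_um = c(310 / 512, 1, 310 / 512)) {
  paths <- sort(list.files(dir, pattern = "\\.tiff?$", full.names = TRUE))
  if (!length(paths)) stop("no TIFF files in ", dir)
  volume_series(lapply(paths, read_volume, pitch_um = pitch_um))
}
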