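# Desk-scale simulation of the wavefront-sensorless correction loop: a
# Zernike-aberrated pupil images an en face scene, and a single round of
# sequential modal optimization (defocus Z4 up to Z15, Noll indexing)
# maximizes image brightness.

# Noll mapping: for radial order n, the indices
# j = n(n+1)/2 + 1 ... (n+1)(n+2)/2 carry |m| ascending; even j -> m >= 0
# (cosine), odd j -> m <= 0 (sine).
noll_nm <- function(j) {
  stopifnot(j >= 1)
  n <- 0
  while ((n + 1) * (n + 2) / 2 < j) n <- n + 1
  pos <- j - n * (n + 1) / 2 # 1-based position within order n
  mabs <- if (n %% 2 == 0) {
    c(0, rep(seq(2, n, by = 2), each = 2))[pos]
  } else {
    rep(seq(1, n, by = 2), each = 2)[pos]
  }
  m <- if (mabs == 0) 0 else if (j %% 2 == 0) mabs else -mabs
  c(n = n, m = m)
}

# Radial polynomial R_n^|m|(rho).
zernike_radial <- function(n, mabs, rho) {
  out <- 0
  for (k in 0:((n - mabs) / 2)) {
    out <- out + (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + mabs) / 2 - k) * factorial((n - mabs) / 2 - k)) *
      rho^(n - 2 * k)
  }
  out
}

#' Noll-normalized Zernike polynomial basis over the unit pupil
#'
#' Each mode has unit RMS over the unit disk (Noll normalization), zero
#' outside. Returned as a list of matrices plus the pupil mask.
#'
#' @param modes integer Noll indices.
#' @param pupil_samples grid size (>= 32).
#' @return list with `basis` (named list of `pupil_samples^2` matrices),
#'   `mask` (logical disk mask).
#' @export
zernike_basis <- function(modes, pupil_samples = 64L) {
  if (pupil_samples < 32L) stop("pupil grid must be >= 32")
  ax <- seq(-1, 1, length.out = pupil_samples)
  X <- outer(rep(1, pupil_samples), ax)
  Y <- outer(ax, rep(1, pupil_samples))
  rho <- sqrt(X^2 + Y^2)
  theta <- atan2(Y, X)
  mask <- rho <= 1
  basis <- lapply(modes, function(j) {
    nm <- noll_nm(j)
    n <- nm["n"]
    m <- nm["m"]
    mabs <- abs(m)
    Rnm <- zernike_radial(n, mabs, rho)
    norm <- if (m == 0) sqrt(n + 1) else sqrt(2 * (n + 1))
    Z <- if (m == 0) {
      norm * Rnm
    } else if (m > 0) {
      norm * Rnm * cos(mabs * theta)
    } else {
      norm * Rnm * sin(mabs * theta)
    }
    Z[!mask] <- 0
    Z
  })
  names(basis) <- paste0("Z", modes)
  list(basis = basis, mask = mask)
}

#' Zernike aberration state
#'
#' Coefficients are radians RMS of pupil phase per mode, Noll indices 4..15
#' (defocus through higher orders, the modes the modal optimization sweeps).
#'
#' @param coeffs named numeric, names `"Z4"`..`"Z15"` (missing modes are 0).
#' @param pupil_samples pupil grid size.
#' @param metric_trace optional data frame of optimization evaluations.
#' @return object of class `zernike_state`.
#' @export
zernike_state <- function(coeffs = numeric(0), pupil_samples = 64L,
                          metric_trace = NULL) {
  full <- setNames(numeric(12), paste0("Z", 4:15))
  if (length(coeffs)) {
    if (is.null(names(coeffs))) stop("`coeffs` must be named Z4..Z15")
    bad <- setdiff(names(coeffs), names(full))
    if (length(bad)) stop("indices restricted to Z4..Z15; unknown: ",
                          paste(bad, collapse = ", "))
    if (any(!is.finite(coeffs))) stop("coefficients must be finite")
    full[names(coeffs)] <- coeffs
  }
  structure(list(coeffs = full, pupil_samples = as.integer(pupil_samples),
                 metric_trace = metric_trace),
            class = "zernike_state")
}

#' @export
print.zernike_state <- function(x, ...) {
  nz <- x$coeffs[x$coeffs != 0]
  cat(sprintf("<zernike_state> RMS %.3f rad; %s\n", wavefront_rms(x),
              if (length(nz)) paste(names(nz), sprintf("%.3f", nz), collapse = " ")
              else "flat"))
  invisible(x)
}

#' Total RMS wavefront error of a Zernike state
#'
#' With Noll normalization the modes are orthonormal over the pupil, so the
#' wavefront RMS is the Euclidean norm of the coefficient vector.
#'
#' @param state a [zernike_state] (or named coefficient vector).
#' @return RMS phase error in radians.
#' @export
wavefront_rms <- function(state) {
  cf <- if (inherits(state, "zernike_state")) state$coeffs else state
  sqrt(sum(cf^2))
}

#' Pupil phase map of a Zernike state
#'
#' Sum of Noll-normalized Zernike polynomials over the unit disk, zero
#' outside.
#'
#' @param coeffs named coefficients (radians RMS) or a [zernike_state].
#' @param pupil_samples grid size.
#' @return `pupil_samples^2` phase matrix in radians.
#' @export
zernike_phase <- function(coeffs, pupil_samples = 64L) {
  if (inherits(coeffs, "zernike_state")) {
    pupil_samples <- coeffs$pupil_samples
    coeffs <- coeffs$coeffs
  }
  coeffs <- coeffs[coeffs != 0]
  phase <- matrix(0, pupil_samples, pupil_samples)
  if (length(coeffs) == 0L) return(phase)
  zb <- zernike_basis(as.integer(sub("^Z", "", names(coeffs))), pupil_samples)
  for (i in seq_along(coeffs)) phase <- phase + coeffs[i] * zb$basis[[i]]
  phase
}

# Strehl ratio of an aberrated pupil: on-axis PSF intensity relative to the
# diffraction-limited pupil, |<exp(i phi)>_disk|^2.
strehl_ratio <- function(phase, mask) {
  Mod(mean(exp(1i * phase[mask])))^2
}

# Centered, unit-sum intensity PSF of the aberrated pupil, embedded in an
# out_dim grid (pupil zero-padded; FFT; intensity; centre at the array
# middle).
psf_from_pupil <- function(phase, mask, out_dim) {
  n <- nrow(phase)
  if (any(out_dim < n)) stop("scene must be at least as large as the pupil grid")
  P <- matrix(0 + 0i, out_dim[1], out_dim[2])
  r0 <- (out_dim[1] - n) %/% 2
  c0 <- (out_dim[2] - n) %/% 2
  P[(r0 + 1):(r0 + n), (c0 + 1):(c0 + n)] <- mask * exp(1i * phase)
  psf <- Mod(fft(P))^2
  psf <- fftshift2(psf)
  psf / sum(psf)
}

fftshift2 <- function(m) {
  d <- dim(m)
  s1 <- d[1] %/% 2
  s2 <- d[2] %/% 2
  m[c((s1 + 1):d[1], 1:s1), c((s2 + 1):d[2], 1:s2)]
}

#' Image an en face scene through an aberrated pupil
#'
#' Incoherent circular convolution of the scene with the pupil's intensity
#' PSF, weighted by the Strehl ratio. The Strehl factor models the signal
#' coupling loss of the confocal double pass: plain incoherent convolution
#' preserves mean brightness, so without it the brightness metric would be
#' blind to aberration. Zero aberration returns the diffraction-limited image
#' with Strehl 1.
#'
#' @param scene non-negative matrix of en face reflectance.
#' @param coeffs named Zernike coefficients or a [zernike_state].
#' @param pupil_samples pupil grid size (ignored for a state input).
#' @param zb optional precomputed [zernike_basis()] for the full mode set
#'   `Z4..Z15` (internal fast path).
#' @return detected image, same size as `scene`.
#' @export
image_through_aberration <- function(scene, coeffs, pupil_samples = 64L, zb = NULL) {
  if (any(scene < 0)) stop("scene must be non-negative")
  if (inherits(coeffs, "zernike_state")) {
    pupil_samples <- coeffs$pupil_samples
    coeffs <- coeffs$coeffs
  }
  full <- setNames(numeric(12), paste0("Z", 4:15))
  full[names(coeffs)] <- coeffs
  if (is.null(zb)) zb <- zernike_basis(4:15, pupil_samples)
  phase <- matrix(0, pupil_samples, pupil_samples)
  for (i in seq_len(12)) {
    if (full[i] != 0) phase <- phase + full[i] * zb$basis[[i]]
  }
  S <- strehl_ratio(phase, zb$mask)
  psf <- psf_from_pupil(phase, zb$mask, dim(scene))
  # circular convolution via FFT with the kernel centred at the origin
  k <- ifftshift2(psf)
  out <- Re(fft(fft(scene) * fft(k), inverse = TRUE)) / length(scene)
  pmax(out, 0) * S
}

ifftshift2 <- function(m) {
  d <- dim(m)
  s1 <- d[1] - d[1] %/% 2
  s2 <- d[2] - d[2] %/% 2
  m[c((s1 + 1):d[1], 1:s1), c((s2 + 1):d[2], 1:s2)]
}

#' Image brightness metric
#'
#' Mean intensity of a detected en face image: the quantity the sensorless
#' optimization maximizes in real time.
#'
#' @param img non-negative matrix.
#' @return scalar mean intensity.
#' @export
brightness_metric <- function(img) {
  if (any(img < 0)) stop("image must be non-negative")
  mean(img)
}

#' One round of sequential sensorless modal optimization
#'
#' For each mode Z4..Z15 in order, the correction coefficient is modulated
#' across a symmetric trial grid, the detected-image brightness is evaluated
#' for `true aberration + correction so far + trial`, and the argmax is kept.
#' Exactly one pass is performed; every evaluation is recorded in the metric
#' trace.
#'
#' @param scene en face reflectance matrix.
#' @param true_aberration a [zernike_state]: the aberration to be corrected.
#' @param search symmetric trial grid in radians (default 9 points over
#'   +-1 rad); must contain >= 5 points and be symmetric about 0.
#' @param modes Noll indices to sweep, in order (default 4:15).
#' @return a [zernike_state] holding the correction, with `metric_trace`
#'   columns `mode, trial, brightness`.
#' @export
sensorless_optimize <- function(scene, true_aberration,
                                search = seq(-1, 1, length.out = 9L),
                                modes = 4:15) {
  stopifnot(inherits(true_aberration, "zernike_state"))
  if (length(search) < 5L) stop("trial grid must have >= 5 points")
  if (max(abs(sort(search) + rev(sort(search)))) > 1e-9) {
    stop("trial grid must be symmetric about 0")
  }
  ps <- true_aberration$pupil_samples
  zb <- zernike_basis(4:15, ps)
  corr <- setNames(numeric(12), paste0("Z", 4:15))
  trace <- vector("list", length(modes))
  search <- sort(search)
  step <- diff(search)[1]
  for (mi in seq_along(modes)) {
    j <- modes[mi]
    key <- paste0("Z", j)
    eval_trial <- function(t) {
      trial <- true_aberration$coeffs + corr
      trial[key] <- trial[key] + t
      brightness_metric(image_through_aberration(scene, trial, ps, zb = zb))
    }
    bright <- vapply(search, eval_trial, numeric(1))
    bi <- which.max(bright)
    pick <- search[bi]
    trials <- search
    # parabolic refinement of the grid argmax: the brightness-vs-coefficient
    # curve is smooth (Strehl-dominated), so the vertex of the 3-point
    # parabola recovers the optimum well below the grid step; the refined
    # trial is kept only if it actually measures brighter, so the running
    # best brightness never decreases
    if (bi > 1 && bi < length(search)) {
      y0 <- bright[bi - 1]; y1 <- bright[bi]; y2 <- bright[bi + 1]
      den <- y0 - 2 * y1 + y2
      if (den < 0) {
        tv <- search[bi] + step * 0.5 * (y0 - y2) / den
        bv <- eval_trial(tv)
        trials <- c(trials, tv)
        bright <- c(bright, bv)
        if (bv >= y1) pick <- tv
      }
    }
    corr[key] <- corr[key] + pick
    trace[[mi]] <- data.frame(mode = j, trial = trials, brightness = bright)
  }
  zernike_state(corr, pupil_samples = ps, metric_trace = do.call(rbind, trace))
}
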