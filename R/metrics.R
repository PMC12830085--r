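# Image-quality metrics: patchwise Tenengrad sharpness and local contrast,
# improvement ratios, speckle contrast, SSIM, line-profile correlation, and
# one-phase exponential decay fits of metric-vs-averaging curves.

# Sum over non-overlapping p x p tiles; trailing partial tiles are dropped.
tile_reduce <- function(m, p, fun = sum) {
  nr <- nrow(m) %/% p
  nc <- ncol(m) %/% p
  if (nr < 1 || nc < 1) stop("patch larger than image")
  m <- m[seq_len(nr * p), seq_len(nc * p), drop = FALSE]
  a <- array(m, dim = c(p, nr, p * nc)) # split rows
  a <- array(aperm(a, c(1, 3, 2)), dim = c(p, p, nc, nr))
  apply(a, c(4, 3), fun)
}

# Sobel gradient magnitude with replicated borders.
sobel_magnitude <- function(img) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3) # d/dcol
  gx <- EBImage::filter2(img, kx, boundary = "replicate")
  gy <- EBImage::filter2(img, t(kx), boundary = "replicate")
  sqrt(gx^2 + gy^2)
}

#' Patchwise Tenengrad sharpness map
#'
#' For each non-overlapping `patch` x `patch` tile, the sum of Sobel gradient
#' magnitudes. Trailing partial tiles are dropped.
#'
#' @param img grayscale matrix.
#' @param patch patch edge in pixels (default 20).
#' @return matrix of per-patch Tenengrad values.
#' @export
tenengrad_map <- function(img, patch = 20L) {
  tile_reduce(sobel_magnitude(img), patch, sum)
}

#' Patchwise local-contrast map (sample standard deviation)
#'
#' Per non-overlapping patch, the intensity standard deviation with the
#' `N - 1` denominator. Trailing partial tiles are dropped.
#'
#' @inheritParams tenengrad_map
#' @return matrix of per-patch standard deviations.
#' @export
contrast_map <- function(img, patch = 20L) {
  tile_reduce(img, patch, stats::sd)
}

#' Mean improvement ratio between two quality maps
#'
#' @param after_map,before_map same-tiling metric maps.
#' @return scalar `mean(after) / mean(before)`.
#' @export
improvement_ratio <- function(after_map, before_map) {
  if (!identical(dim(after_map), dim(before_map))) {
    stop("maps must share one tiling")
  }
  b <- mean(before_map, na.rm = TRUE)
  if (!is.finite(b) || b == 0) stop("before-map mean is zero")
  mean(after_map, na.rm = TRUE) / b
}

#' Speckle contrast
#'
#' `C = sigma / mu` over the region, with the population standard deviation.
#' Fully developed speckle (exponential intensity) has `C = 1`; averaging `N`
#' independent realizations lowers it towards `1/sqrt(N)`.
#'
#' @param x numeric vector, matrix or array of intensities (the ROI).
#' @return scalar `C >= 0`.
#' @export
speckle_contrast <- function(x) {
  x <- as.numeric(x)
  mu <- mean(x)
  if (!is.finite(mu) || mu <= 0) stop("ROI mean must be positive")
  sqrt(mean((x - mu)^2)) / mu
}

#' Normalized speckle contrast across an averaging series
#'
#' Computes `C(N) / C(1)` for a set of averaged images indexed by the number
#' of averaged volumes `N`; the entry at `N = 1` is exactly 1 by construction.
#'
#' @param avg_images list of images (matrices or arrays), one per `N`.
#' @param N integer vector of averaging counts, same length; must contain 1.
#' @param roi optional `list(rows =, cols =)` restricting matrices to an ROI.
#' @return data frame with columns `N`, `C`, `C_norm`, sorted by `N`.
#' @export
normalized_speckle_series <- function(avg_images, N, roi = NULL) {
  stopifnot(length(avg_images) == length(N))
  if (!any(N == 1)) stop("the series must include the single-volume entry N = 1")
  pick <- function(img) {
    if (is.null(roi)) img else img[roi$rows, roi$cols, drop = FALSE]
  }
  C <- vapply(avg_images, function(img) speckle_contrast(pick(img)), numeric(1))
  o <- order(N)
  C <- C[o]
  N <- N[o]
  data.frame(N = N, C = C, C_norm = C / C[N == 1][1])
}

#' Structural similarity index (SSIM)
#'
#' Standard SSIM with an 11 x 11 Gaussian weighting window (sigma 1.5),
#' `K1 = 0.01`, `K2 = 0.03`, dynamic range taken from the reference image.
#' The map is evaluated where the window fits entirely inside the image and
#' its mean is returned; the value lies in `[-1, 1]`.
#'
#' @param img,ref equal-size matrices; `ref` is the reference.
#' @param sigma,win Gaussian window parameters.
#' @param K1,K2 stabilizing constants.
#' @return scalar SSIM.
#' @export
ssim <- function(img, ref, sigma = 1.5, win = 11L, K1 = 0.01, K2 = 0.03) {
  if (!identical(dim(img), dim(ref))) stop("images must have the same shape")
  if (nrow(img) < win || ncol(img) < win) stop("image smaller than SSIM window")
  L <- diff(range(ref))
  if (L == 0) stop("reference has zero dynamic range")
  r <- (win - 1L) / 2
  g <- exp(-((-r):r)^2 / (2 * sigma^2))
  w <- outer(g, g)
  w <- w / sum(w)
  f <- function(m) EBImage::filter2(m, w, boundary = "circular")
  mu1 <- f(img)
  mu2 <- f(ref)
  s11 <- f(img^2) - mu1^2
  s22 <- f(ref^2) - mu2^2
  s12 <- f(img * ref) - mu1 * mu2
  C1 <- (K1 * L)^2
  C2 <- (K2 * L)^2
  map <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
    ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
  interior <- map[(r + 1):(nrow(map) - r), (r + 1):(ncol(map) - r)]
  mean(interior)
}

#' Intensity profile along a line segment
#'
#' Unit-spacing bilinear samples from `p0` to `p1` (both `c(row, col)`,
#' 1-based, inside the image). The same coordinates can be reused across a
#' series of images.
#'
#' @param img matrix.
#' @param p0,p1 segment endpoints `c(row, col)`.
#' @return numeric profile including both endpoints.
#' @export
line_profile <- function(img, p0, p1) {
  p0 <- as.numeric(p0)
  p1 <- as.numeric(p1)
  len <- sqrt(sum((p1 - p0)^2))
  if (len == 0) stop("endpoints coincide")
  inside <- function(p) {
    p[1] >= 1 && p[1] <= nrow(img) && p[2] >= 1 && p[2] <= ncol(img)
  }
  if (!inside(p0) || !inside(p1)) stop("endpoints must lie inside the image")
  t <- c(seq(0, len, by = 1), if (len %% 1 != 0) len) / len
  rq <- p0[1] + t * (p1[1] - p0[1])
  cq <- p0[2] + t * (p1[2] - p0[2])
  bilinear_sample(img, rq, cq)
}

#' Pearson correlation between a profile and a reference profile
#'
#' @param profile,ref_profile equal-length numeric vectors (length >= 3).
#' @return Pearson r.
#' @export
profile_correlation <- function(profile, ref_profile) {
  if (length(profile) != length(ref_profile)) stop("profiles must match in length")
  if (length(profile) < 3L) stop("profiles must have length >= 3")
  if (stats::sd(profile) == 0 || stats::sd(ref_profile) == 0) {
    stop("zero-variance profile")
  }
  stats::cor(profile, ref_profile)
}

#' One-phase exponential decay fit of a metric-vs-averaging curve
#'
#' Least-squares fit of `y(N) = plateau + (y0 - plateau) * exp(-(N - 1)/tau)`,
#' parameterized so `y(1) = y0` exactly. Works for decaying and saturating
#' (increasing) metrics alike.
#'
#' @param N_values averaging counts (>= 1), at least 4 points.
#' @param y_values metric values.
#' @return An object of class `decay_fit`: `y0`, `plateau`, `tau`, `rss`,
#'   `identifiable` (FALSE for constant data, where `tau` is `NA`).
#' @export
fit_exponential_decay <- function(N_values, y_values) {
  stopifnot(length(N_values) == length(y_values), length(N_values) >= 4L)
  if (any(N_values < 1)) stop("N values must be >= 1")
  o <- order(N_values)
  N <- as.numeric(N_values[o])
  y <- as.numeric(y_values[o])
  if (max(y) - min(y) < .Machine$double.eps^0.5 * max(1, abs(y[1]))) {
    fit <- list(y0 = y[1], plateau = y[1], tau = NA_real_, rss = 0,
                identifiable = FALSE)
    return(structure(fit, class = "decay_fit"))
  }
  span <- diff(range(N))
  starts <- list(
    c(y0 = y[1], plateau = y[length(y)], tau = span / 3),
    c(y0 = y[1], plateau = y[length(y)], tau = span / 10),
    c(y0 = y[1], plateau = y[length(y)], tau = span)
  )
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ plateau + (y0 - plateau) * exp(-(N - 1) / tau),
        start = as.list(s),
        lower = c(y0 = -Inf, plateau = -Inf, tau = 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(resid(fit)^2)
      if (is.null(best) || rss < best$rss) {
        cf <- coef(fit)
        best <- list(y0 = unname(cf["y0"]), plateau = unname(cf["plateau"]),
                     tau = unname(cf["tau"]), rss = rss, identifiable = TRUE)
      }
    }
  }
  if (is.null(best)) stop("exponential decay fit failed to converge")
  structure(best, class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> y0=%.4g plateau=%.4g tau=%.4g rss=%.3g%s\n",
              x$y0, x$plateau, x$tau, x$rss,
              if (!x$identifiable) " (tau unidentifiable)" else ""))
  invisible(x)
}
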