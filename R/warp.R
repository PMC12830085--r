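# Interpolating warps shared by the synthetic motion model and the
# registration correction step. All warps move CONTENT by the given shift:
# positive shift moves structure towards larger indices. Voxels whose source
# falls outside the original grid are returned as NA with valid = FALSE.

#' Shift an array along one axis by a (possibly fractional) amount
#'
#' Linear interpolation; content moves by `+s` along `axis`. Entries sourced
#' from outside the array are `NA` and flagged invalid.
#'
#' @param a numeric array (2-D or 3-D).
#' @param axis axis index to shift along.
#' @param s signed shift in voxels.
#' @return list with `data` (shifted array, `NA` outside) and `valid`
#'   (logical array).
#' @keywords internal
axis_shift <- function(a, axis, s) {
  d <- dim(a)
  n <- d[axis]
  if (abs(s) >= n) stop("shift exceeds array extent along axis ", axis)
  k <- floor(s)
  f <- s - k
  take <- function(offset) {
    # slab[i] = a[i - offset] along `axis`, NA outside
    idx <- seq_len(n) - offset
    ok <- idx >= 1 & idx <= n
    idx[!ok] <- 1L
    args <- rep(list(quote(expr = )), length(d))
    args[[axis]] <- idx
    out <- do.call(`[`, c(list(a), args, list(drop = FALSE)))
    if (any(!ok)) {
      args[[axis]] <- which(!ok)
      out <- do.call(`[<-`, c(list(out), args, list(value = NA_real_)))
    }
    out
  }
  out <- if (f == 0) take(k) else (1 - f) * take(k) + f * take(k + 1)
  list(data = out, valid = !is.na(out))
}

#' Bilinear sampling of a matrix at fractional coordinates
#'
#' @param m matrix.
#' @param rq,cq equal-length numeric vectors of fractional row/column query
#'   coordinates (1-based).
#' @return numeric vector; `NA` where the 2x2 neighbourhood leaves the matrix.
#' @keywords internal
bilinear_sample <- function(m, rq, cq) {
  nr <- nrow(m)
  nc <- ncol(m)
  r0 <- floor(rq)
  c0 <- floor(cq)
  fr <- rq - r0
  fc <- cq - c0
  # allow exact hits on the last row/col
  atr <- r0 == nr & fr == 0
  atc <- c0 == nc & fc == 0
  ok <- (r0 >= 1 & c0 >= 1) & (r0 + 1 <= nr | atr) & (c0 + 1 <= nc | atc)
  r0c <- pmin(pmax(r0, 1L), nr - 1L)
  c0c <- pmin(pmax(c0, 1L), nc - 1L)
  frc <- rq - r0c
  fcc <- cq - c0c
  i00 <- cbind(r0c, c0c)
  v <- (1 - frc) * (1 - fcc) * m[i00] +
    frc * (1 - fcc) * m[cbind(r0c + 1L, c0c)] +
    (1 - frc) * fcc * m[cbind(r0c, c0c + 1L)] +
    frc * fcc * m[cbind(r0c + 1L, c0c + 1L)]
  v[!ok] <- NA_real_
  v
}

#' Rigid warp of a B-scan plane
#'
#' Rotates content by `rot_deg` about the image centre, then translates it by
#' `(dz, dx)` (rows, columns). Output pixels sourced from outside the input
#' are `NA`/invalid.
#'
#' @param m matrix indexed `(z, x)`.
#' @param dx,dz translation in columns (x) and rows (z).
#' @param rot_deg rotation in degrees (content rotation, about the centre).
#' @return list with `data` and `valid`.
#' @keywords internal
warp_plane_rigid <- function(m, dx = 0, dz = 0, rot_deg = 0) {
  nr <- nrow(m)
  nc <- ncol(m)
  if (rot_deg == 0 && dx == 0 && dz == 0) {
    return(list(data = m, valid = matrix(TRUE, nr, nc)))
  }
  cz <- (nr + 1) / 2
  cx <- (nc + 1) / 2
  th <- -rot_deg * pi / 180 # inverse mapping
  zz <- rep(seq_len(nr), times = nc)
  xx <- rep(seq_len(nc), each = nr)
  z0 <- zz - cz - dz
  x0 <- xx - cx - dx
  zs <- cos(th) * z0 - sin(th) * x0 + cz
  xs <- sin(th) * z0 + cos(th) * x0 + cx
  v <- bilinear_sample(m, zs, xs)
  data <- matrix(v, nr, nc)
  list(data = data, valid = !is.na(data))
}

#' Parameters of the inverse rigid transform
#'
#' For the rigid warp "rotate by `rot` about the centre then translate by
#' `(dx, dz)`", returns parameters `(dx', dz', rot')` of the inverse in the
#' same parameterization.
#'
#' @param dx,dz,rot_deg forward transform parameters.
#' @return named numeric `c(dx, dz, rot_deg)`.
#' @keywords internal
invert_rigid <- function(dx, dz, rot_deg) {
  th <- -rot_deg * pi / 180
  # inverse: rotate by -rot, translate by -R(-rot) %*% t
  dzi <- -(cos(th) * dz - sin(th) * dx)
  dxi <- -(sin(th) * dz + cos(th) * dx)
  c(dx = dxi, dz = dzi, rot_deg = -rot_deg)
}

# Gaussian smoothing with replicated borders.
gauss_smooth <- function(m, sigma) {
  r <- ceiling(3 * sigma)
  if (min(dim(m)) <= 2 * r + 1) return(m)
  g <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- outer(g, g)
  EBImage::filter2(m, k / sum(k), boundary = "replicate")
}

# Replace NA entries with the mean of the finite ones (used before FFTs).
fill_na_mean <- function(m) {
  if (anyNA(m)) {
    mu <- mean(m, na.rm = TRUE)
    if (!is.finite(mu)) mu <- 0
    m[is.na(m)] <- mu
  }
  m
}
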