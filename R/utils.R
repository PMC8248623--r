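# Internal numerical helpers shared across modules.
# Convention everywhere: matrices are image-style (rows = y, increasing
# downward; columns = x). Physical x maps to columns, y to rows.

## angular FFT frequencies (rad per unit length) for an n-point axis with
## sample spacing d, in standard DFT order.
fftKvec <- function(n, d = 1) {
  idx <- c(seq.int(0L, ceiling(n / 2) - 1L), seq.int(-floor(n / 2), -1L))
  2 * pi * idx / (n * d)
}

## matrices of kx (varying along columns) and ky (along rows)
fftKgrid <- function(nr, nc, d = 1) {
  kx <- fftKvec(nc, d)
  ky <- fftKvec(nr, d)
  list(kx = matrix(kx, nr, nc, byrow = TRUE),
       ky = matrix(ky, nr, nc, byrow = FALSE))
}

## subpixel cyclic shift of a real matrix by (dx, dy) pixels via the Fourier
## phase ramp; shifted(x) = img(x - dx, y - dy) (content moves by +d).
fourierShift <- function(img, dx, dy) {
  nr <- nrow(img); nc <- ncol(img)
  kx <- fftKvec(nc, 1); ky <- fftKvec(nr, 1)
  ## zero the Nyquist phase for even sizes so the output stays real-symmetric
  if (nc %% 2 == 0) kx[nc / 2 + 1] <- 0
  if (nr %% 2 == 0) ky[nr / 2 + 1] <- 0
  phase <- exp(-1i * (outer(ky * dy, rep(1, nc)) + outer(rep(1, nr), kx * dx)))
  Re(stats::fft(stats::fft(img) * phase, inverse = TRUE)) / (nr * nc)
}

## map a DFT peak index (1-based) to a signed shift
dftIndexToShift <- function(i, n) {
  s <- i - 1L
  ifelse(s > n / 2, s - n, s)
}

## bilinear interpolation of matrix z (rows = y, cols = x) at physical points
## (px, py), given grid spacing and origin; NA outside the grid.
bilinearAt <- function(z, px, py, spacing = 1, origin = c(0, 0)) {
  cx <- (px - origin[1]) / spacing + 1
  cy <- (py - origin[2]) / spacing + 1
  nr <- nrow(z); nc <- ncol(z)
  out <- rep(NA_real_, length(px))
  ok <- cx >= 1 & cx <= nc & cy >= 1 & cy <= nr & is.finite(cx) & is.finite(cy)
  if (!any(ok)) return(out)
  cx <- cx[ok]; cy <- cy[ok]
  x0 <- pmin(floor(cx), nc - 1); y0 <- pmin(floor(cy), nr - 1)
  fx <- cx - x0; fy <- cy - y0
  v <- z[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
       z[cbind(y0, x0 + 1)] * fx * (1 - fy) +
       z[cbind(y0 + 1, x0)] * (1 - fx) * fy +
       z[cbind(y0 + 1, x0 + 1)] * fx * fy
  out[ok] <- v
  out
}

## separable Gaussian smoothing with reflected boundaries; sigma in pixels
gaussianSmooth <- function(z, sigma) {
  if (sigma <= 0) return(z)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  smooth1 <- function(m) {      # along rows (y direction)
    n <- nrow(m)
    idx <- c(rev(seq_len(min(r, n))), seq_len(n), n + 1 - rev(seq_len(min(r, n))))
    if (r > n) idx <- pmax(1L, pmin(n, c(rep(1L, r - n), idx, rep(n, r - n))))
    mp <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * mp[j:(j + n - 1), , drop = FALSE]
    out
  }
  t(smooth1(t(smooth1(z))))
}

## Chebyshev (square structuring element) binary dilation by `px` pixels;
## keeps an expanded square patch square, matching how a user-drawn traction
## area is grown by a margin.
dilateMask <- function(mask, px) {
  px <- as.integer(round(px))
  if (px <= 0) return(mask)
  d <- EBImage::dilate(mask * 1, EBImage::makeBrush(2L * px + 1L, shape = "box"))
  matrix(d > 0.5, nrow(mask), ncol(mask))
}

## fill interior holes of a mask (regions of background not connected to the
## image border); returns the filled mask
fillHoles <- function(mask) {
  f <- EBImage::fillHull(mask * 1)
  matrix(f > 0.5, nrow(mask), ncol(mask))
}

## number of 4-connected components of a logical mask (label diffusion)
connectedComponents <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- seq_len(sum(mask))
  nr <- nrow(lab); nc <- ncol(lab)
  repeat {
    nb <- lab
    nb <- pmax(nb, rbind(lab[-1, , drop = FALSE], 0L))
    nb <- pmax(nb, rbind(0L, lab[-nr, , drop = FALSE]))
    nb <- pmax(nb, cbind(lab[, -1, drop = FALSE], 0L))
    nb <- pmax(nb, cbind(0L, lab[, -nc, drop = FALSE]))
    nb[!mask] <- 0L
    if (identical(nb, lab)) break
    lab <- nb
  }
  length(unique(lab[mask]))
}

## physical pixel-center coordinate vectors (um) for a field stored in an
## nr x nc matrix with given spacing/origin
gridCoords <- function(nr, nc, spacing, origin = c(0, 0)) {
  list(x = origin[1] + (seq_len(nc) - 1) * spacing,
       y = origin[2] + (seq_len(nr) - 1) * spacing)
}
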