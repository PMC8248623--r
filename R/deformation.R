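# Substrate deformation from bead-image pairs: sub-pixel global drift
# correction by upsampled cross-correlation, then window-wise zero-mean
# normalized cross-correlation PIV with 3-point Gaussian sub-pixel peak
# refinement and signal-to-noise based outlier replacement.

#' PIV parameters
#'
#' @param windowSize interrogation window edge length in pixels.
#' @param overlap overlap between neighbouring windows in pixels
#'   (0 <= overlap < windowSize).
#' @param snrThreshold minimum ratio between the highest correlation peak and
#'   the second-highest peak found outside a 2-pixel neighbourhood of the
#'   first; vectors below it are replaced (default 1.03).
#' @param replacementRadius radius, in deformation-grid points, of the
#'   neighbourhood whose valid vectors replace an outlier by their mean
#'   (default 2).
#' @return a list of class \code{"pivParams"}.
#' @examples
#' pivParams(windowSize = 50, overlap = 25)
#' @export
pivParams <- function(windowSize = 50, overlap = windowSize / 2,
                      snrThreshold = 1.03, replacementRadius = 2) {
  windowSize <- as.integer(windowSize)
  overlap <- as.integer(overlap)
  stopifnot(windowSize > 0, overlap >= 0, overlap < windowSize,
            snrThreshold >= 1, replacementRadius >= 0)
  structure(list(windowSize = windowSize, overlap = overlap,
                 snrThreshold = snrThreshold,
                 replacementRadius = replacementRadius),
            class = "pivParams")
}

## cross-correlation surface via FFT; peak index s means a(x) ~ b(x - s)
crossCorrelation <- function(a, b) {
  fa <- stats::fft(a)
  fb <- stats::fft(b)
  Re(stats::fft(fa * Conj(fb), inverse = TRUE)) / length(a)
}

## refine an integer shift to 1/upsample px by matrix-multiply DFT of the
## cross-power spectrum in a +/- 1.5 px neighbourhood (Guizar-Sicairos
## upsampled image registration)
upsampledShift <- function(R, shift, upsample = 100) {
  nr <- nrow(R); nc <- ncol(R)
  half <- 1.5
  sy <- shift[2] + seq(-half, half, by = 1 / upsample)
  sx <- shift[1] + seq(-half, half, by = 1 / upsample)
  fy <- c(seq.int(0L, ceiling(nr / 2) - 1L), seq.int(-floor(nr / 2), -1L))
  fx <- c(seq.int(0L, ceiling(nc / 2) - 1L), seq.int(-floor(nc / 2), -1L))
  Ey <- exp(2i * pi * outer(sy, fy) / nr)
  Ex <- exp(2i * pi * outer(fx, sx) / nc)
  CC <- Re(Ey %*% R %*% Ex)
  pk <- which(CC == max(CC), arr.ind = TRUE)[1, ]
  c(sx[pk[2]], sy[pk[1]])
}

#' Sub-pixel drift correction of an image pair
#'
#' Estimates the global translation between the tensed and relaxed images by
#' cross-correlating the full images (refined to 1/100 px by upsampled DFT
#' evaluation of the correlation around its peak), shifts the tensed image
#' by the negated drift via the Fourier phase ramp, and crops both images to
#' the overlapping field of view.
#'
#' @param pair an \linkS4class{ImagePair}.
#' @param upsample sub-pixel refinement factor (default 100).
#' @return list with the corrected \code{pair} and \code{drift}
#'   \code{c(x, y)} in pixels (displacement of the tensed image relative to
#'   the relaxed one).
#' @export
correctDrift <- function(pair, upsample = 100) {
  stopifnot(is(pair, "ImagePair"))
  A <- pair@tensed; B <- pair@relaxed
  if (stats::var(as.vector(A)) == 0 || stats::var(as.vector(B)) == 0)
    stop("no texture for registration")
  R <- stats::fft(A - mean(A)) * Conj(stats::fft(B - mean(B)))
  cc <- Re(stats::fft(R, inverse = TRUE)) / length(A)
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  s0 <- c(dftIndexToShift(pk[2], ncol(A)), dftIndexToShift(pk[1], nrow(A)))
  drift <- upsampledShift(R, s0, upsample)
  if (all(drift == 0))
    return(list(pair = pair, drift = c(x = 0, y = 0)))
  ## align the tensed image onto the relaxed one
  Ac <- fourierShift(A, -drift[1], -drift[2])
  cx <- ceiling(abs(drift[1])); cy <- ceiling(abs(drift[2]))
  rows <- if (drift[2] >= 0) seq_len(nrow(A) - cy) else (cy + 1):nrow(A)
  cols <- if (drift[1] >= 0) seq_len(ncol(A) - cx) else (cx + 1):ncol(A)
  out <- imagePair(Ac[rows, cols, drop = FALSE], B[rows, cols, drop = FALSE],
                   pair@pixelSize)
  list(pair = out, drift = c(x = drift[1], y = drift[2]))
}

## Gaussian 3-point sub-pixel interpolation along one axis of a correlation
## peak; falls back to parabolic interpolation for non-positive values
peakInterp <- function(cm, cp, c0) {
  if (c0 > 0 && cm > 0 && cp > 0 && (cm != c0 || cp != c0)) {
    den <- 2 * log(cm) - 4 * log(c0) + 2 * log(cp)
    if (den < 0) return((log(cm) - log(cp)) / den)
  }
  den <- 2 * (cm - 2 * c0 + cp)
  if (den < 0) (cm - cp) / den else 0
}

#' Deformation field by cross-correlation PIV
#'
#' Lays interrogation windows on a regular grid with step
#' \code{windowSize - overlap}, cross-correlates each zero-mean normalized
#' tensed window against the corresponding relaxed window, takes the
#' correlation peak within half a window of zero shift, and refines it to
#' sub-pixel accuracy with a 3-point Gaussian fit in x and y. Vectors whose
#' peak-to-second-peak ratio falls below \code{snrThreshold} (the second
#' peak is searched outside a 2-pixel neighbourhood of the first) are
#' replaced by the local mean of valid vectors within
#' \code{replacementRadius} grid points.
#'
#' @param pair a drift-corrected \linkS4class{ImagePair}.
#' @param params a [pivParams()].
#' @return deformation \linkS4class{VectorField2D} in um, one vector per
#'   window, with attribute \code{"nReplaced"} counting replaced outliers.
#' @export
computeDeformation <- function(pair, params = pivParams()) {
  stopifnot(is(pair, "ImagePair"), inherits(params, "pivParams"))
  w <- params$windowSize
  step <- w - params$overlap
  nr <- nrow(pair@tensed); nc <- ncol(pair@tensed)
  if (w > nr || w > nc) stop("interrogation window larger than image")
  r0 <- seq(1, nr - w + 1, by = step)
  c0 <- seq(1, nc - w + 1, by = step)
  P <- 2L * w                      # zero-padded correlation size
  maxShift <- floor(w / 2)
  vxm <- matrix(NA_real_, length(r0), length(c0))
  vym <- matrix(NA_real_, length(r0), length(c0))
  snr <- matrix(NA_real_, length(r0), length(c0))
  Ap <- matrix(0, P, P); Bp <- matrix(0, P, P)
  for (i in seq_along(r0)) for (j in seq_along(c0)) {
    A <- pair@tensed[r0[i]:(r0[i] + w - 1), c0[j]:(c0[j] + w - 1)]
    B <- pair@relaxed[r0[i]:(r0[i] + w - 1), c0[j]:(c0[j] + w - 1)]
    sa <- stats::sd(A); sb <- stats::sd(B)
    if (sa == 0 || sb == 0) next
    Ap[] <- 0; Bp[] <- 0
    Ap[1:w, 1:w] <- (A - mean(A)) / sa
    Bp[1:w, 1:w] <- (B - mean(B)) / sb
    cc <- crossCorrelation(Ap, Bp)
    ## compensate the triangular overlap weighting of the zero-padded
    ## correlation (removes the bias of large shifts toward zero)
    shAll <- c(seq.int(0, P / 2 - 1), seq.int(-P / 2, -1))
    ov <- pmax(w - abs(shAll), 1) / w
    cc <- cc / outer(ov, ov)
    ## wrap to centred shifts and restrict the search
    sh <- shAll
    ok <- abs(sh) <= maxShift
    sub <- cc[ok, ok, drop = FALSE]
    shSub <- sh[ok]
    pk <- which(sub == max(sub), arr.ind = TRUE)
    pk <- pk[order(pk[, 1], pk[, 2]), , drop = FALSE][1, ]  # ties: smaller index
    peak1 <- sub[pk[1], pk[2]]
    dy0 <- shSub[pk[1]]; dx0 <- shSub[pk[2]]
    ## second peak outside a 2-px neighbourhood of the first
    dmat <- outer(abs(shSub - dy0), abs(shSub - dx0), pmax)
    away <- dmat > 2
    peak2 <- if (any(away)) max(sub[away]) else NA_real_
    snr[i, j] <- if (!is.na(peak2) && peak2 > 0) peak1 / peak2 else Inf
    ## sub-pixel refinement from the full wrapped correlation surface
    iy <- ((dy0 %% P)) + 1L
    ix <- ((dx0 %% P)) + 1L
    ym <- ((dy0 - 1) %% P) + 1L; yp <- ((dy0 + 1) %% P) + 1L
    xm <- ((dx0 - 1) %% P) + 1L; xp <- ((dx0 + 1) %% P) + 1L
    ddy <- peakInterp(cc[ym, ix], cc[yp, ix], cc[iy, ix])
    ddx <- peakInterp(cc[iy, xm], cc[iy, xp], cc[iy, ix])
    vxm[i, j] <- (dx0 + ddx) * pair@pixelSize
    vym[i, j] <- (dy0 + ddy) * pair@pixelSize
  }
  valid <- is.finite(vxm) & is.finite(vym) & is.finite(snr) &
           snr >= params$snrThreshold
  if (!any(valid)) stop("deformation field unrecoverable")
  nReplaced <- sum(!valid)
  res <- replaceOutliers(vxm, vym, valid, params$replacementRadius)
  ctr <- (w - 1) / 2               # window centre offset, 0-based px
  field <- vectorField2D(res$vx, res$vy,
                         spacing = step * pair@pixelSize,
                         origin = c((c0[1] - 1 + ctr) * pair@pixelSize,
                                    (r0[1] - 1 + ctr) * pair@pixelSize),
                         units = "um")
  attr(field, "nReplaced") <- nReplaced
  field
}

## replace invalid vectors by the mean of valid vectors within a Euclidean
## grid-distance radius; iterate so replaced vectors can seed later passes
replaceOutliers <- function(vx, vy, valid, radius) {
  nr <- nrow(vx); nc <- ncol(vx)
  off <- expand.grid(dy = -floor(radius):floor(radius),
                     dx = -floor(radius):floor(radius))
  off <- off[off$dy^2 + off$dx^2 <= radius^2 &
             !(off$dy == 0 & off$dx == 0), , drop = FALSE]
  bad <- which(!valid, arr.ind = TRUE)
  vx[!valid] <- NA; vy[!valid] <- NA
  while (nrow(bad) > 0) {
    filledAny <- FALSE
    stillBad <- matrix(integer(0), 0, 2)
    newVx <- vx; newVy <- vy
    for (b in seq_len(nrow(bad))) {
      yy <- bad[b, 1] + off$dy
      xx <- bad[b, 2] + off$dx
      keep <- yy >= 1 & yy <= nr & xx >= 1 & xx <= nc
      vals <- cbind(vx[cbind(yy[keep], xx[keep])],
                    vy[cbind(yy[keep], xx[keep])])
      vals <- vals[is.finite(vals[, 1]), , drop = FALSE]
      if (nrow(vals) > 0) {
        newVx[bad[b, 1], bad[b, 2]] <- mean(vals[, 1])
        newVy[bad[b, 1], bad[b, 2]] <- mean(vals[, 2])
        filledAny <- TRUE
      } else {
        stillBad <- rbind(stillBad, bad[b, , drop = FALSE])
      }
    }
    vx <- newVx; vy <- newVy
    bad <- stillBad
    if (!filledAny && nrow(bad) > 0) {
      ## isolated cluster beyond the radius: fall back to the global mean
      vx[bad] <- mean(vx[is.finite(vx)])
      vy[bad] <- mean(vy[is.finite(vy)])
      break
    }
  }
  list(vx = vx, vy = vy)
}
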