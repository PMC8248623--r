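# Fourier Transform Traction Cytometry: the displacement field u of the
# substrate surface and the traction field t exerted on it are related by a
# convolution with the elastic Green's tensor, which becomes a per-wavevector
# 2x2 multiplication in Fourier space. The forward map (traction ->
# deformation) and the inverse map (FTTC proper) share the same kernel.

## finite-thickness correction factors for an elastic layer of thickness h
## bonded to a rigid base, relative to the half-space (Boussinesq) solution.
## s = k*h. Transverse (antiplane shear) mode: tanh(s). Longitudinal
## (plane-strain) mode: ((3-4v) sinh s cosh s + s) /
##                      ((3-4v) cosh^2 s + (1-2v)^2 + s^2).
## Both tend to 1 as s -> Inf; the longitudinal factor is the reciprocal of
## the classical layer stiffening term used in finite-thickness traction
## microscopy.
layerFactorTransverse <- function(s) {
  f <- tanh(s)
  f[s > 30] <- 1
  f
}

layerFactorLongitudinal <- function(s, nu) {
  f <- s  # placeholder, overwritten below
  big <- s > 30
  sm <- !big
  ss <- s[sm]
  a <- 3 - 4 * nu
  f[sm] <- (a * sinh(ss) * cosh(ss) + ss) /
           (a * cosh(ss)^2 + (1 - 2 * nu)^2 + ss^2)
  f[big] <- 1
  f
}

#' Fourier-space Green's tensor of the substrate surface
#'
#' Computes the 2x2 tensor \eqn{\tilde K(k)} relating the Fourier transforms
#' of the surface traction and the surface displacement,
#' \eqn{\tilde u = \tilde K \tilde t}. For an infinitely thick substrate this
#' is the Boussinesq half-space tensor
#' \deqn{\tilde K = \frac{2(1+\nu)}{E k^3}
#'   \begin{pmatrix} (1-\nu)k^2 + \nu k_y^2 & -\nu k_x k_y \\
#'                   -\nu k_x k_y & (1-\nu)k^2 + \nu k_x^2 \end{pmatrix}.}
#' For a finite thickness \eqn{h} (layer bonded to a rigid support) the
#' transverse and longitudinal eigenmodes of the tensor are multiplied by
#' thickness-dependent factors that approach 1 as \eqn{kh \to \infty}.
#'
#' @param kx,ky matrices of angular wavevector components (rad/um), e.g. from
#'   an FFT frequency grid.
#' @param substrate an \linkS4class{ElasticSubstrate}.
#' @return list with matrices \code{Kxx}, \code{Kyy}, \code{Kxy} (um/Pa);
#'   the \eqn{k = 0} entry is \code{NA} and must be handled by the caller.
#' @examples
#' kg <- monolayerTFM:::fftKgrid(8, 8, d = 1)
#' K <- greensTensor(kg$kx, kg$ky, elasticSubstrate(1000, 0.5))
#' @export
greensTensor <- function(kx, ky, substrate) {
  stopifnot(is(substrate, "ElasticSubstrate"))
  validObject(substrate)
  if (length(kx) == 0) stop("empty frequency grid")
  E <- substrate@young
  nu <- substrate@poisson
  h <- substrate@thickness
  k2 <- kx^2 + ky^2
  k <- sqrt(k2)
  if (is.infinite(h)) {
    ft <- 1
    fl <- 1
  } else {
    s <- k * h
    ft <- layerFactorTransverse(s)
    fl <- layerFactorLongitudinal(s, nu)
  }
  pref <- 2 * (1 + nu) / (E * k)
  hx2 <- kx^2 / k2  # direction cosines squared
  hy2 <- ky^2 / k2
  hxy <- kx * ky / k2
  Kxx <- pref * (ft * hy2 + (1 - nu) * fl * hx2)
  Kyy <- pref * (ft * hx2 + (1 - nu) * fl * hy2)
  Kxy <- pref * hxy * ((1 - nu) * fl - ft)
  zero <- k2 == 0
  Kxx[zero] <- NA_real_
  Kyy[zero] <- NA_real_
  Kxy[zero] <- NA_real_
  list(Kxx = Kxx, Kyy = Kyy, Kxy = Kxy)
}

## shared plumbing: optionally zero-pad a pair of component matrices to at
## least double the linear size, apply a per-wavevector 2x2 operation in
## Fourier space, transform back and crop.
applyFourierKernel <- function(mx, my, spacing, substrate, pad, inverse) {
  nr0 <- nrow(mx); nc0 <- ncol(mx)
  if (pad) {
    nr <- 2 * nr0; nc <- 2 * nc0
    px <- matrix(0, nr, nc); py <- matrix(0, nr, nc)
    px[seq_len(nr0), seq_len(nc0)] <- mx
    py[seq_len(nr0), seq_len(nc0)] <- my
  } else {
    nr <- nr0; nc <- nc0
    px <- mx; py <- my
  }
  kg <- fftKgrid(nr, nc, d = spacing)
  K <- greensTensor(kg$kx, kg$ky, substrate)
  fx <- stats::fft(px)
  fy <- stats::fft(py)
  if (inverse) {
    det <- K$Kxx * K$Kyy - K$Kxy^2
    ox <- (K$Kyy * fx - K$Kxy * fy) / det
    oy <- (K$Kxx * fy - K$Kxy * fx) / det
  } else {
    ox <- K$Kxx * fx + K$Kxy * fy
    oy <- K$Kxy * fx + K$Kyy * fy
  }
  ## k = 0: undefined kernel; null the mean mode (global force balance /
  ## field defined up to rigid translation)
  ox[1, 1] <- 0
  oy[1, 1] <- 0
  rx <- Re(stats::fft(ox, inverse = TRUE)) / (nr * nc)
  ry <- Re(stats::fft(oy, inverse = TRUE)) / (nr * nc)
  list(x = rx[seq_len(nr0), seq_len(nc0)], y = ry[seq_len(nr0), seq_len(nc0)])
}

#' Forward map: substrate deformation generated by a traction field
#'
#' Evaluates \eqn{\tilde u = \tilde K \tilde t} on the FFT grid of the input
#' and transforms back. The zero-frequency displacement is set to zero (the
#' field is defined up to a rigid translation).
#'
#' @param t a \linkS4class{VectorField2D} of tractions in Pa.
#' @param substrate an \linkS4class{ElasticSubstrate}.
#' @param pad zero-pad to twice the linear size before the FFT and crop
#'   afterwards. The default \code{FALSE} evaluates the periodic problem,
#'   which makes the pair of Fourier maps exactly inverse to each other.
#' @return deformation \linkS4class{VectorField2D} in um on the same grid.
#' @seealso [tractionFromDeformation()]
#' @export
deformationFromTraction <- function(t, substrate, pad = FALSE) {
  stopifnot(is(t, "VectorField2D"))
  if (any(!is.finite(t@vx)) || any(!is.finite(t@vy)))
    stop("non-finite traction input")
  net <- c(sum(t@vx), sum(t@vy))
  scale <- sum(abs(t@vx)) + sum(abs(t@vy))
  if (scale > 0 && max(abs(net)) / scale > 1e-6)
    warning("net traction is not balanced; ",
            "deformation is defined only up to a rigid translation")
  out <- applyFourierKernel(t@vx, t@vy, t@spacing, substrate,
                            pad = pad, inverse = FALSE)
  vectorField2D(out$x, out$y, spacing = t@spacing, origin = t@origin,
                units = "um")
}

#' Fourier Transform Traction Cytometry (deformation to traction)
#'
#' Inverts the surface Green's tensor per wavevector,
#' \eqn{\tilde t = \tilde K^{-1} \tilde u}, nulls the zero-frequency mode
#' (global force balance), and optionally low-pass filters the resulting
#' traction components with a Gaussian of width \code{filterSigma}. With
#' \code{filterSigma = 0} and \code{pad = FALSE} the operation is the exact
#' algebraic inverse of [deformationFromTraction()].
#'
#' @param u a \linkS4class{VectorField2D} of deformations in um.
#' @param substrate an \linkS4class{ElasticSubstrate}.
#' @param filterSigma Gaussian smoothing width in um applied to the traction
#'   components after inversion (typically 3 um); 0 disables smoothing.
#' @param pad see [deformationFromTraction()].
#' @return traction \linkS4class{VectorField2D} in Pa on the same grid.
#' @export
tractionFromDeformation <- function(u, substrate, filterSigma = 3,
                                    pad = FALSE) {
  stopifnot(is(u, "VectorField2D"))
  if (any(!is.finite(u@vx)) || any(!is.finite(u@vy)))
    stop("non-finite deformation input")
  if (filterSigma < 0) stop("'filterSigma' must be >= 0")
  out <- applyFourierKernel(u@vx, u@vy, u@spacing, substrate,
                            pad = pad, inverse = TRUE)
  tx <- out$x; ty <- out$y
  if (filterSigma > 0) {
    sig <- filterSigma / u@spacing
    tx <- gaussianSmooth(tx, sig)
    ty <- gaussianSmooth(ty, sig)
  }
  vectorField2D(tx, ty, spacing = u@spacing, origin = u@origin, units = "Pa")
}
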