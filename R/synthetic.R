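# Synthetic ground truth: an analytically defined contractile cell patch
# (uniform biaxial sheet stress on a centred square), the traction field it
# must exert on the substrate by force balance, the substrate deformation
# field from the forward Fourier map, and rendered bead-image pairs for
# end-to-end testing of the PIV stage.

#' Specification of the synthetic square-patch experiment
#'
#' Bundles every parameter of the synthetic validation chain. Defaults are
#' the reference conditions: a 150 um wide square patch carrying a uniform
#' biaxial normal sheet stress on a 400 x 400 um field sampled at 1 um per
#' pixel, on a 100 um thick substrate, with 3 um Gaussian traction
#' smoothing.
#'
#' @param fieldSize linear size of the simulated field of view (um).
#' @param spacing grid spacing (um per pixel).
#' @param patchWidth width L of the square patch (um); must be < fieldSize.
#' @param sigma0 magnitude of the uniform normal sheet stress (N/m). The
#'   absolute scale cancels from every normalized recovery metric.
#' @param young,poisson,thickness substrate elastic constants (Pa, -, um).
#' @param filterSigma Gaussian traction smoothing width for the inverse step
#'   (um).
#' @param beadDensity bead number density for image rendering (beads/px^2).
#' @param psfSigma point-spread (spot) width for rendered beads (px).
#' @param seed integer seed fixing all randomness of the rendering step.
#' @return a list of class \code{"syntheticSpec"}.
#' @examples
#' sp <- syntheticSpec(fieldSize = 128, patchWidth = 50)
#' @export
syntheticSpec <- function(fieldSize = 400, spacing = 1, patchWidth = 150,
                          sigma0 = 1, young = 49000, poisson = 0.5,
                          thickness = 100, filterSigma = 3,
                          beadDensity = 0.02, psfSigma = 1.5, seed = 1L) {
  stopifnot(patchWidth < fieldSize, spacing > 0, sigma0 > 0)
  structure(list(fieldSize = fieldSize, spacing = spacing,
                 patchWidth = patchWidth, sigma0 = sigma0,
                 substrate = elasticSubstrate(young, poisson, thickness),
                 filterSigma = filterSigma, beadDensity = beadDensity,
                 psfSigma = psfSigma, seed = as.integer(seed)),
            class = "syntheticSpec")
}

#' Analytic square-patch stress field
#'
#' Uniform biaxial normal stress (\eqn{\sigma_{xx} = \sigma_{yy} = \sigma_0},
#' zero shear) inside a centred square of width \code{patchWidth}, zero
#' outside.
#'
#' @param spec a [syntheticSpec()].
#' @return A \linkS4class{StressTensorField} whose \code{mask} marks the
#'   patch.
#' @export
makeSquareStress <- function(spec) {
  n <- round(spec$fieldSize / spec$spacing)
  cc <- gridCoords(n, n, spec$spacing)
  ctr <- spec$fieldSize / 2 - spec$spacing / 2  # centre in origin-at-first-pixel coords
  inX <- abs(cc$x - ctr) <= spec$patchWidth / 2
  inY <- abs(cc$y - ctr) <= spec$patchWidth / 2
  inside <- outer(inY, inX, "&")
  s <- matrix(0, n, n)
  s[inside] <- spec$sigma0
  stressTensorField(sxx = s, syy = s, sxy = matrix(0, n, n),
                    spacing = spec$spacing, mask = inside)
}

#' Traction field balancing a sheet-stress field
#'
#' Applies the two-dimensional force balance between the sheet stress and
#' the traction the sheet exerts on its substrate,
#' \eqn{t_x = \partial\sigma_{xx}/\partial x + \partial\sigma_{yx}/\partial y}
#' (and analogously for \eqn{t_y}), with central finite differences. The
#' sign convention is the standard cell-on-substrate one: for a tensile
#' (contractile) patch the tractions form inward-pointing (centripetal)
#' bands along the patch edges, and the reaction forces \eqn{-t} load the
#' finite-element sheet model.
#'
#' @param sigma a \linkS4class{StressTensorField} (components in N/m).
#' @return traction \linkS4class{VectorField2D} in Pa on the same grid.
#' @export
tractionFromStress <- function(sigma) {
  stopifnot(is(sigma, "StressTensorField"))
  a <- sigma@spacing * 1e-6  # um -> m
  sxx <- sigma@sxx; syy <- sigma@syy; sxy <- sigma@sxy
  sxx[is.na(sxx)] <- 0; syy[is.na(syy)] <- 0; sxy[is.na(sxy)] <- 0
  ddx <- function(m) {
    nc <- ncol(m)
    d <- (cbind(m[, -1, drop = FALSE], m[, nc]) -
          cbind(m[, 1], m[, -nc, drop = FALSE])) / (2 * a)
    d[, 1] <- (m[, 2] - m[, 1]) / a
    d[, nc] <- (m[, nc] - m[, nc - 1]) / a
    d
  }
  ddy <- function(m) t(ddx(t(m)))
  tx <- ddx(sxx) + ddy(sxy)
  ty <- ddx(sxy) + ddy(syy)
  vectorField2D(tx, ty, spacing = sigma@spacing, origin = sigma@origin,
                units = "Pa")
}

#' Render a bead-image pair from a deformation field
#'
#' Draws Gaussian spots at uniformly random positions (the relaxed,
#' force-free substrate) and the same spots displaced by the deformation
#' field interpolated at each spot (the tensed substrate), so that particle
#' image velocimetry on the pair should recover the input field.
#'
#' @param u deformation \linkS4class{VectorField2D} in um.
#' @param spec a [syntheticSpec()]; uses \code{beadDensity}, \code{psfSigma},
#'   \code{seed} and \code{spacing}.
#' @param imageDim optional c(rows, cols) of the rendered images; defaults to
#'   the deformation grid dimensions.
#' @return an \linkS4class{ImagePair}.
#' @export
renderBeadImages <- function(u, spec, imageDim = dim(u)) {
  stopifnot(is(u, "VectorField2D"))
  if (spec$beadDensity <= 0) stop("bead density must be > 0")
  nr <- imageDim[1]; nc <- imageDim[2]
  px <- spec$spacing
  set.seed(spec$seed)
  nb <- max(1L, round(spec$beadDensity * nr * nc))
  bx <- runif(nb, 0.5, nc - 0.5)   # pixel coordinates (0-based centres)
  by <- runif(nb, 0.5, nr - 0.5)
  amp <- runif(nb, 0.6, 1)
  ## displacement (um -> px) at each bead, zero where outside the field
  ux <- bilinearAt(u@vx, bx * px, by * px, u@spacing, u@origin) / px
  uy <- bilinearAt(u@vy, bx * px, by * px, u@spacing, u@origin) / px
  ux[is.na(ux)] <- 0
  uy[is.na(uy)] <- 0
  relaxed <- renderSpots(bx, by, amp, nr, nc, spec$psfSigma)
  tensed <- renderSpots(bx + ux, by + uy, amp, nr, nc, spec$psfSigma)
  top <- max(relaxed, tensed, 1e-12)
  imagePair(tensed = tensed / top, relaxed = relaxed / top, pixelSize = px)
}

## accumulate Gaussian spots onto an image grid (pixel centres at 0.5, 1.5, ...)
renderSpots <- function(bx, by, amp, nr, nc, sigma) {
  img <- matrix(0, nr, nc)
  r <- ceiling(4 * sigma)
  xs <- seq_len(nc) - 0.5
  ys <- seq_len(nr) - 0.5
  for (i in seq_along(bx)) {
    c0 <- max(1L, floor(bx[i] - r)); c1 <- min(nc, ceiling(bx[i] + r) + 1L)
    r0 <- max(1L, floor(by[i] - r)); r1 <- min(nr, ceiling(by[i] + r) + 1L)
    if (c0 > c1 || r0 > r1) next
    gx <- exp(-(xs[c0:c1] - bx[i])^2 / (2 * sigma^2))
    gy <- exp(-(ys[r0:r1] - by[i])^2 / (2 * sigma^2))
    img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + amp[i] * outer(gy, gx)
  }
  img
}

#' Run the full synthetic square-patch validation chain
#'
#' Builds the analytic stress field, derives the balancing traction field,
#' forward-computes the substrate deformation with the finite-thickness
#' kernel, reconstructs tractions by FTTC with Gaussian smoothing, and
#' recovers the monolayer stress on an FEM grid expanded by \code{margin}
#' beyond the patch. Scalar recovery metrics are evaluated over the original
#' patch area (stresses) and over a configurable expanded area
#' (contractility).
#'
#' @param spec a [syntheticSpec()].
#' @param margin FEM-grid expansion margin beyond the patch outline (um).
#' @param contractilityMargin expansion of the area over which contractility
#'   is compared between input and recovered tractions (um).
#' @return list with the intermediate fields (\code{stress}, \code{traction},
#'   \code{deformation}, \code{tractionRecovered}, \code{stressRecovered}),
#'   the patch mask, and scalar summaries: \code{recovery} (mean normal
#'   stress over the patch / sigma0), \code{cvInput}, \code{cvRecovered},
#'   \code{contractilityInput}, \code{contractilityRecovered} (N).
#' @export
squarePatchExperiment <- function(spec, margin = 5, contractilityMargin = 12) {
  sigma <- makeSquareStress(spec)
  trac <- tractionFromStress(sigma)
  u <- deformationFromTraction(trac, spec$substrate)
  tracRec <- tractionFromDeformation(u, spec$substrate,
                                     filterSigma = spec$filterSigma)
  patch <- sigma@mask
  marginPx <- round(margin / spec$spacing)
  femMask <- dilateMask(patch, marginPx)
  msm <- monolayerStress(tracRec, femMask, spacing = spec$spacing)
  mnRec <- meanNormalStress(msm$stress)
  inPatch <- patch & msm$stress@mask
  recovery <- mean(mnRec[inPatch]) / spec$sigma0
  cvRec <- stats::sd(mnRec[inPatch]) / mean(mnRec[inPatch])
  cMask <- dilateMask(patch, round(contractilityMargin / spec$spacing))
  cIn <- contractility(trac, cMask)
  cRec <- contractility(tracRec, cMask)
  list(stress = sigma, traction = trac, deformation = u,
       tractionRecovered = tracRec, stressRecovered = msm$stress,
       patchMask = patch, femMask = femMask, alpha = msm$alpha,
       recovery = recovery, cvInput = 0, cvRecovered = cvRec,
       contractilityInput = cIn$contractility,
       contractilityRecovered = cRec$contractility)
}

#' Scan the FEM-grid expansion margin on the synthetic test
#'
#' Repeats the synthetic recovery for a range of expansion margins and
#' reports the normalized mean normal stress over the patch and the
#' contractility over each expanded area, reproducing the characteristic
#' rise-then-slow-decline of stress recovery versus traction-area size.
#'
#' @param spec a [syntheticSpec()].
#' @param margins numeric vector of margins (um).
#' @return data.frame with columns \code{margin}, \code{recovery}
#'   (normalized mean normal stress) and \code{contractility} (N).
#' @export
scanExpansion <- function(spec, margins = 0:20) {
  sigma <- makeSquareStress(spec)
  trac <- tractionFromStress(sigma)
  u <- deformationFromTraction(trac, spec$substrate)
  tracRec <- tractionFromDeformation(u, spec$substrate,
                                     filterSigma = spec$filterSigma)
  patch <- sigma@mask
  res <- lapply(margins, function(m) {
    femMask <- dilateMask(patch, round(m / spec$spacing))
    msm <- monolayerStress(tracRec, femMask, spacing = spec$spacing)
    mn <- meanNormalStress(msm$stress)
    inPatch <- patch & msm$stress@mask
    co <- contractility(tracRec, femMask)
    c(recovery = mean(mn[inPatch]) / spec$sigma0,
      contractility = co$contractility)
  })
  res <- do.call(rbind, res)
  data.frame(margin = margins, recovery = res[, "recovery"],
             contractility = res[, "contractility"])
}

#' Write the full synthetic fixture set to a directory
#'
#' Emits the analytic stress field, traction and deformation fields (as
#' \code{.rds} arrays and CSV summaries), the rendered bead-image pair
#' (16-bit TIFF) and a ground-truth CSV, for use as pipeline input.
#'
#' @param spec a [syntheticSpec()].
#' @param dir output directory (created if needed).
#' @return invisibly, the list of written file paths.
#' @export
syntheticFixture <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sigma <- makeSquareStress(spec)
  trac <- tractionFromStress(sigma)
  u <- deformationFromTraction(trac, spec$substrate)
  pair <- renderBeadImages(u, spec)
  paths <- c(
    stress = file.path(dir, "stress_true.rds"),
    traction = file.path(dir, "traction_true.rds"),
    deformation = file.path(dir, "deformation_true.rds"),
    tensed = file.path(dir, "tensed.tif"),
    relaxed = file.path(dir, "relaxed.tif"),
    mask = file.path(dir, "mask.png"),
    truth = file.path(dir, "ground_truth.csv"))
  saveRDS(sigma, paths["stress"])
  saveRDS(trac, paths["traction"])
  saveRDS(u, paths["deformation"])
  writeGrayImage(pair@tensed, paths["tensed"])
  writeGrayImage(pair@relaxed, paths["relaxed"])
  ## label image: 1 = traction area (patch + 5 um), 2 = cell patch
  lab <- matrix(0L, nrow(sigma@mask), ncol(sigma@mask))
  lab[dilateMask(sigma@mask, round(5 / spec$spacing))] <- 1L
  lab[sigma@mask] <- 2L
  writeGrayImage(lab / 255, paths["mask"])
  truth <- data.frame(quantity = c("sigma0_Nm", "patch_width_um",
                                   "field_size_um", "spacing_um"),
                      value = c(spec$sigma0, spec$patchWidth,
                                spec$fieldSize, spec$spacing))
  write.table(truth, paths["truth"], sep = ",", row.names = FALSE,
              quote = FALSE)
  invisible(paths)
}
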