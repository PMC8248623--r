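# Scalar measures of force generation, stress magnitude/heterogeneity and
# cell-cell force transmission, reduced from the deformation, traction and
# stress fields over user-selected masks.

#' Per-pixel mean normal stress
#'
#' \eqn{(\sigma_1 + \sigma_2)/2 = (\sigma_{xx} + \sigma_{yy})/2}, the
#' rotation-invariant isotropic part of the 2D stress tensor.
#'
#' @param sigma a \linkS4class{StressTensorField}.
#' @return matrix in N/m (NA outside the valid mask).
#' @export
meanNormalStress <- function(sigma) {
  (sigma@sxx + sigma@syy) / 2
}

#' Substrate strain energy
#'
#' Elastic energy stored in the substrate,
#' \eqn{U = \frac{1}{2} \sum_{\mathrm{area}} \vec u \cdot \vec t \, a^2},
#' with \eqn{u} in m, \eqn{t} in Pa and pixel side \eqn{a} in m.
#'
#' @param u deformation \linkS4class{VectorField2D} (um).
#' @param t traction \linkS4class{VectorField2D} (Pa) on the same grid.
#' @param mask logical matrix selecting the integration area (default: all).
#' @return strain energy in joules.
#' @export
strainEnergy <- function(u, t, mask = NULL) {
  stopifnot(is(u, "VectorField2D"), is(t, "VectorField2D"))
  if (!all(dim(u@vx) == dim(t@vx)) || u@spacing != t@spacing)
    stop("deformation and traction fields must share the same grid")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(u@vx), ncol(u@vx))
  aSI <- u@spacing * 1e-6
  dot <- (u@vx * t@vx + u@vy * t@vy) * 1e-6  # um * Pa -> m * Pa
  0.5 * sum(dot[mask]) * aSI^2
}

#' Contractility and force epicenter
#'
#' The force epicenter is the point minimizing the summed squared moments
#' \eqn{\sum_i |\vec F_i \times (\vec r_e - \vec r_i)|^2} of the pixel forces
#' \eqn{\vec F_i = \vec t_i a^2} (a linear least-squares problem).
#' Contractility is the sum of all forces projected onto the unit vectors
#' pointing from each pixel towards the epicenter; centripetal (inward
#' pulling) force fields give positive contractility.
#'
#' @param t traction \linkS4class{VectorField2D} (Pa).
#' @param mask logical matrix selecting the evaluation area (default: all).
#' @return list with \code{epicenter} (x, y in um) and \code{contractility}
#'   in N.
#' @export
contractility <- function(t, mask = NULL) {
  stopifnot(is(t, "VectorField2D"))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(t@vx), ncol(t@vx))
  aSI <- t@spacing * 1e-6
  idx <- which(mask, arr.ind = TRUE)
  cc <- gridCoords(nrow(t@vx), ncol(t@vx), t@spacing, t@origin)
  xi <- cc$x[idx[, 2]] * 1e-6  # m
  yi <- cc$y[idx[, 1]] * 1e-6
  Fx <- t@vx[idx] * aSI^2
  Fy <- t@vy[idx] * aSI^2
  ## residual_i(xe, ye) = Fx_i*ye - Fy_i*xe - (Fx_i*y_i - Fy_i*x_i):
  ## linear least squares in (xe, ye). Solved about the force-weighted
  ## centroid with a pseudo-inverse so that a direction left undetermined by
  ## the force lines (e.g. a single pair of collinear opposing forces)
  ## resolves to the centroid along that direction.
  w <- sqrt(Fx^2 + Fy^2)
  if (sum(w) == 0) stop("degenerate epicenter system: no forces")
  x0 <- sum(w * xi) / sum(w); y0 <- sum(w * yi) / sum(w)
  xc <- xi - x0; yc <- yi - y0
  A <- matrix(c(sum(Fy^2), -sum(Fx * Fy), -sum(Fx * Fy), sum(Fx^2)), 2, 2)
  b <- c(-sum(Fy * (Fx * yc - Fy * xc)), sum(Fx * (Fx * yc - Fy * xc)))
  ev <- eigen(A, symmetric = TRUE)
  keep <- ev$values > 1e-12 * max(ev$values)
  if (!any(keep))
    stop("degenerate epicenter system: force lines of action have no ",
         "well-defined common intersection")
  co <- ev$vectors[, keep, drop = FALSE] %*%
    ((crossprod(ev$vectors[, keep, drop = FALSE], b)) / ev$values[keep])
  xe <- x0 + co[1]
  ye <- y0 + co[2]
  dx <- xe - xi; dy <- ye - yi
  dn <- sqrt(dx^2 + dy^2)
  ok <- dn > 0
  C <- sum((Fx[ok] * dx[ok] + Fy[ok] * dy[ok]) / dn[ok])
  list(epicenter = c(x = xe * 1e6, y = ye * 1e6), contractility = C)
}

#' Scalar stress measures over a cell mask
#'
#' Principal stresses \eqn{\sigma_1 \ge \sigma_2} are computed per pixel from
#' the 2x2 tensor; the maximum normal stress is \eqn{\sigma_1}, the maximum
#' shear stress \eqn{(\sigma_1 - \sigma_2)/2}, and the mean normal stress
#' \eqn{(\sigma_1 + \sigma_2)/2}. Averages are taken over the mask; the
#' coefficient of variation is sd/mean of the per-pixel mean normal stress.
#'
#' @param sigma a \linkS4class{StressTensorField}.
#' @param mask logical matrix (default: the field's valid mask).
#' @return named list: \code{avgMaxNormalStress}, \code{avgMaxShearStress},
#'   \code{avgMeanNormalStress} (N/m) and \code{cvNormalStress}.
#' @export
stressScalars <- function(sigma, mask = NULL) {
  stopifnot(is(sigma, "StressTensorField"))
  if (is.null(mask)) mask <- sigma@mask
  mask <- mask & sigma@mask
  if (!any(mask)) stop("empty mask")
  mn <- meanNormalStress(sigma)[mask]
  r <- sqrt(((sigma@sxx - sigma@syy) / 2)^2 + sigma@sxy^2)[mask]
  list(avgMaxNormalStress = mean(mn + r),
       avgMaxShearStress = mean(r),
       avgMeanNormalStress = mean(mn),
       cvNormalStress = stats::sd(mn) / mean(mn))
}

#' Line tension along cell-cell boundaries
#'
#' For every segment of every boundary polyline, the tension vector is
#' \eqn{\vec T = \sigma \cdot \hat n} (N/m) with the stress tensor
#' interpolated bilinearly at the segment midpoint and \eqn{\hat n} the unit
#' normal of the segment. The normal component \eqn{\vec T \cdot \hat n}
#' keeps its sign (tension vs. compression); the shear component is reported
#' as a magnitude. Averages are length-weighted over all segments. Segments
#' whose midpoint falls outside the valid stress region are skipped with a
#' warning.
#'
#' @param sigma a \linkS4class{StressTensorField}.
#' @param boundaries list of polylines, each a 2-column matrix of (x, y)
#'   vertices in um with at least 2 rows.
#' @return list with \code{segments} (data.frame: midpoint, normal, tension
#'   components, length) and length-weighted \code{avgLineTension},
#'   \code{avgNormalLineTension}, \code{avgShearLineTension} (N/m).
#' @export
lineTension <- function(sigma, boundaries) {
  stopifnot(is(sigma, "StressTensorField"), is.list(boundaries))
  segs <- list()
  for (b in seq_along(boundaries)) {
    P <- as.matrix(boundaries[[b]])
    if (nrow(P) < 2) stop("polylines must have at least 2 vertices")
    i <- seq_len(nrow(P) - 1)
    mx <- (P[i, 1] + P[i + 1, 1]) / 2
    my <- (P[i, 2] + P[i + 1, 2]) / 2
    ex <- P[i + 1, 1] - P[i, 1]
    ey <- P[i + 1, 2] - P[i, 2]
    len <- sqrt(ex^2 + ey^2)
    tx <- ex / len; ty <- ey / len
    nx <- ty; ny <- -tx             # tangent rotated -90 deg (y down)
    sxx <- bilinearAt(sigma@sxx, mx, my, sigma@spacing, sigma@origin)
    syy <- bilinearAt(sigma@syy, mx, my, sigma@spacing, sigma@origin)
    sxy <- bilinearAt(sigma@sxy, mx, my, sigma@spacing, sigma@origin)
    segs[[b]] <- data.frame(boundary = b, mx = mx, my = my, nx = nx, ny = ny,
                            sxx = sxx, syy = syy, sxy = sxy, length = len)
  }
  s <- do.call(rbind, segs)
  bad <- !is.finite(s$sxx) | !is.finite(s$syy) | !is.finite(s$sxy)
  if (any(bad)) {
    warning(sprintf("%d segment(s) outside the valid stress region skipped",
                    sum(bad)))
    s <- s[!bad, , drop = FALSE]
  }
  if (nrow(s) == 0) stop("no boundary segment lies inside the stress field")
  Tx <- s$sxx * s$nx + s$sxy * s$ny
  Ty <- s$sxy * s$nx + s$syy * s$ny
  s$tensionX <- Tx
  s$tensionY <- Ty
  s$magnitude <- sqrt(Tx^2 + Ty^2)
  s$normal <- Tx * s$nx + Ty * s$ny
  s$shear <- -(Tx * s$ny) + Ty * s$nx   # component along the tangent
  w <- s$length / sum(s$length)
  list(segments = s,
       avgLineTension = sum(w * s$magnitude),
       avgNormalLineTension = sum(w * s$normal),
       avgShearLineTension = sum(w * abs(s$shear)))
}

#' Assemble the scalar results record
#'
#' Collects the standard scalar outputs of a full analysis into a named
#' record matching the conventional result-table rows.
#'
#' @param u,t deformation and traction fields.
#' @param stress recovered \linkS4class{StressTensorField}.
#' @param tractionMask traction-area mask (strain energy, contractility).
#' @param cellMask cell-patch mask (stress averages); defaults to
#'   \code{tractionMask}.
#' @param boundaries optional list of cell-cell boundary polylines.
#' @param nCells optional user-supplied cell count for normalization.
#' @return named list of scalars with units documented in
#'   [writeResults()].
#' @export
resultsRecord <- function(u, t, stress, tractionMask, cellMask = NULL,
                          boundaries = NULL, nCells = NULL) {
  if (is.null(cellMask)) cellMask <- tractionMask
  if (!is.null(cellMask) && !is.null(tractionMask) &&
      any(cellMask & !tractionMask))
    warning("cell patch mask is not contained in the traction area mask")
  sc <- stressScalars(stress, cellMask)
  co <- contractility(t, tractionMask)
  rec <- list(
    "Contractility" = co$contractility,
    "Strain energy" = strainEnergy(u, t, tractionMask),
    "Avg. max. normal stress" = sc$avgMaxNormalStress,
    "Avg. max. shear stress" = sc$avgMaxShearStress,
    "Avg. mean normal stress" = sc$avgMeanNormalStress,
    "CV normal stress" = sc$cvNormalStress,
    "Cell patch area" = sum(cellMask) * stress@spacing^2)
  if (!is.null(boundaries)) {
    lt <- lineTension(stress, boundaries)
    rec <- c(rec, list(
      "Avg. line tension" = lt$avgLineTension,
      "Avg. normal line tension" = lt$avgNormalLineTension,
      "Avg. shear line tension" = lt$avgShearLineTension))
  }
  if (!is.null(nCells)) rec <- c(rec, list("Cell count" = nCells))
  rec
}

resultUnits <- c(
  "Contractility" = "N", "Strain energy" = "J",
  "Avg. max. normal stress" = "N/m", "Avg. max. shear stress" = "N/m",
  "Avg. mean normal stress" = "N/m", "CV normal stress" = "",
  "Cell patch area" = "um2", "Avg. line tension" = "N/m",
  "Avg. normal line tension" = "N/m", "Avg. shear line tension" = "N/m",
  "Cell count" = "")

#' Write, read and compare scalar result files
#'
#' Results are stored as a tab-separated text file with columns
#' \code{quantity}, \code{value}, \code{unit}, one row per scalar.
#' \code{readResults} reads one or more such files into a long data.frame;
#' \code{compareResults} summarizes each quantity per file group and, when
#' exactly two groups are given, adds Welch t-test p-values.
#'
#' @param record named list from [resultsRecord()].
#' @param path file path of the tab-separated results file.
#' @return \code{writeResults} returns \code{path} invisibly;
#'   \code{readResults} a data.frame with columns file, quantity, value,
#'   unit; \code{compareResults} a per-quantity summary data.frame.
#' @export
writeResults <- function(record, path) {
  df <- data.frame(quantity = names(record),
                   value = unname(unlist(record)),
                   unit = unname(resultUnits[names(record)]),
                   stringsAsFactors = FALSE)
  df$unit[is.na(df$unit)] <- ""
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeResults
#' @param paths character vector of results files.
#' @export
readResults <- function(paths) {
  out <- lapply(paths, function(p) {
    df <- read.table(p, sep = "\t", header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE)
    df$file <- p
    df
  })
  do.call(rbind, out)
}

#' @rdname writeResults
#' @param results long data.frame from [readResults()].
#' @param group optional factor assigning each file to a group; defaults to
#'   one group per file.
#' @export
compareResults <- function(results, group = NULL) {
  if (is.null(group)) {
    results$group <- results$file
  } else {
    map <- stats::setNames(as.character(group), unique(results$file))
    results$group <- map[results$file]
  }
  qs <- unique(results$quantity)
  rows <- lapply(qs, function(q) {
    sub <- results[results$quantity == q, ]
    agg <- stats::aggregate(value ~ group, data = sub, FUN = mean)
    sds <- stats::aggregate(value ~ group, data = sub,
                            FUN = function(v) if (length(v) > 1) sd(v) else NA)
    out <- data.frame(quantity = q, group = agg$group, mean = agg$value,
                      sd = sds$value)
    if (length(unique(sub$group)) == 2 &&
        all(table(sub$group) >= 2)) {
      p <- stats::t.test(value ~ group, data = sub)$p.value
      out$p.value <- p
    }
    out
  })
  do.call(rbind, rows)
}
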