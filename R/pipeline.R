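# Pipeline orchestration: read a YAML run configuration, execute the
# enabled stages (deformation -> traction -> stress -> metrics), and write
# arrays, plots and the tab-separated results file.

#' Read a grayscale image as a matrix
#'
#' Reads TIFF or PNG (8/16-bit) via EBImage; multi-channel images are
#' averaged to grayscale. The returned matrix is image-style (rows = y,
#' columns = x), intensities in [0, 1].
#'
#' @param path image file path.
#' @return numeric matrix.
#' @export
readGrayImage <- function(path) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  a <- EBImage::imageData(img)
  if (length(d) == 3) a <- apply(a, c(1, 2), mean)
  ## EBImage stores x as first dimension; transpose to rows = y
  t(a)
}

#' @rdname readGrayImage
#' @param img numeric matrix in [0, 1] (rows = y, columns = x).
#' @export
writeGrayImage <- function(img, path) {
  EBImage::writeImage(EBImage::Image(t(pmin(pmax(img, 0), 1))), path,
                      bits.per.sample = 16L)
  invisible(path)
}

#' Read a label-image mask set
#'
#' Interprets an integer label image (0 = background, 1 = traction area,
#' 2 = cell patch; the cell patch is implicitly part of the traction area).
#' Intensity levels are mapped to labels by rank, so 8- and 16-bit encodings
#' of 0/1/2 are both accepted.
#'
#' @param path label image path.
#' @return list with logical matrices \code{tractionArea} and
#'   \code{cellPatch} (NULL when the image holds fewer than 3 levels).
#' @export
readMaskSet <- function(path) {
  img <- readGrayImage(path)
  lev <- sort(unique(as.vector(img)))
  if (length(lev) > 3)
    stop("mask image has more than 3 intensity levels; expected labels 0/1/2")
  lab <- matrix(match(img, lev) - 1L, nrow(img), ncol(img))
  list(tractionArea = lab >= 1L,
       cellPatch = if (length(lev) == 3) lab == 2L else NULL)
}

#' Read cell-cell boundary polylines
#'
#' CSV with columns \code{boundary}, \code{x}, \code{y} (um); vertices of
#' each polyline in drawing order.
#'
#' @param path CSV file path.
#' @return list of 2-column (x, y) matrices.
#' @export
readBoundaries <- function(path) {
  df <- read.table(path, sep = ",", header = TRUE)
  stopifnot(all(c("boundary", "x", "y") %in% names(df)))
  lapply(split(df, df$boundary), function(s) cbind(x = s$x, y = s$y))
}

#' Read and validate a pipeline run configuration
#'
#' YAML file with keys: \code{images} (tensed, relaxed, optional cell),
#' \code{masks} (labels, optional boundaries), \code{parameters}
#' (pixel_size, young, poisson, thickness, sigma_um, window_size, overlap,
#' snr_threshold, optional n_cells) and \code{stages} (subset of
#' deformation, traction, stress, metrics forming a prefix of that chain).
#' All lengths are um; conversion to pixels happens once at load.
#'
#' @param path YAML configuration path.
#' @return validated configuration list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (is.null(p) || file.exists(p)) p else
    file.path(base, p)
  cfg$images <- lapply(cfg$images, resolve)
  cfg$masks <- lapply(cfg$masks, resolve)
  chain <- c("deformation", "traction", "stress", "metrics")
  if (is.null(cfg$stages)) cfg$stages <- chain
  if (!all(cfg$stages %in% chain))
    stop("unknown stage(s): ", paste(setdiff(cfg$stages, chain), collapse = ", "))
  k <- max(match(cfg$stages, chain))
  if (!setequal(cfg$stages, chain[seq_len(k)]))
    stop("enabled stages must form a prefix of: ",
         paste(chain, collapse = " -> "))
  cfg$stages <- chain[seq_len(k)]
  for (f in c("tensed", "relaxed")) {
    if (is.null(cfg$images[[f]])) stop("config lacks images$", f)
    if (!file.exists(cfg$images[[f]]))
      stop("missing image file: ", cfg$images[[f]])
  }
  p <- cfg$parameters
  defaults <- list(pixel_size = 1, young = 49000, poisson = 0.5,
                   thickness = Inf, sigma_um = 3, window_size = 50,
                   overlap = 25, snr_threshold = 1.03)
  for (nm in names(defaults)) if (is.null(p[[nm]])) p[[nm]] <- defaults[[nm]]
  cfg$parameters <- p
  cfg
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages on the configured inputs and writes, per
#' stage, field arrays (\code{.rds}), quiver/heat-map plots (PNG) and
#' finally the tab-separated results file. Deterministic given identical
#' inputs.
#'
#' @param config a configuration list from [readRunConfig()] or the path of
#'   a YAML configuration file.
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the computed objects (\code{deformation},
#'   \code{traction}, \code{stress}, \code{results} as available).
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) config <- readRunConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  p <- config$parameters
  out <- list()

  pair <- imagePair(readGrayImage(config$images$tensed),
                    readGrayImage(config$images$relaxed),
                    pixelSize = p$pixel_size)
  dc <- correctDrift(pair)
  message(sprintf("drift: (%.2f, %.2f) px", dc$drift[1], dc$drift[2]))

  u <- computeDeformation(dc$pair, pivParams(p$window_size, p$overlap,
                                             p$snr_threshold))
  saveRDS(u, file.path(outDir, "deformation.rds"))
  plotQuiver(u, file.path(outDir, "deformation.png"),
             main = "substrate deformation (um)")
  out$deformation <- u
  if (!"traction" %in% config$stages) {
    return(invisible(out))
  }

  substrate <- elasticSubstrate(p$young, p$poisson, p$thickness)
  tr <- tractionFromDeformation(u, substrate, filterSigma = p$sigma_um)
  saveRDS(tr, file.path(outDir, "traction.rds"))
  plotHeat(fieldMagnitude(tr), tr@spacing, file.path(outDir, "traction.png"),
           main = "traction magnitude (Pa)")
  out$traction <- tr
  if (!"stress" %in% config$stages) return(invisible(out))

  if (is.null(config$masks$labels))
    stop("stage 'stress' requires masks$labels (traction-area label image)")
  masks <- readMaskSet(config$masks$labels)
  ## masks are drawn on the image pixel grid; resample to the PIV grid
  tmask <- resampleMask(masks$tractionArea, pair, tr)
  msm <- monolayerStress(tr, tmask, spacing = tr@spacing)
  saveRDS(msm$stress, file.path(outDir, "stress.rds"))
  plotHeat(meanNormalStress(msm$stress), msm$stress@spacing,
           file.path(outDir, "mean_normal_stress.png"),
           main = "mean normal stress (N/m)")
  out$stress <- msm$stress
  if (!"metrics" %in% config$stages) return(invisible(out))

  cmask <- if (!is.null(masks$cellPatch))
    resampleMask(masks$cellPatch, pair, tr) else NULL
  boundaries <- if (!is.null(config$masks$boundaries))
    readBoundaries(config$masks$boundaries) else NULL
  rec <- resultsRecord(u, tr, msm$stress, tractionMask = tmask,
                       cellMask = cmask, boundaries = boundaries,
                       nCells = p$n_cells)
  writeResults(rec, file.path(outDir, "results.txt"))
  out$results <- rec
  invisible(out)
}

## nearest-neighbour resampling of an image-resolution mask onto the grid of
## a (coarser) vector field
resampleMask <- function(mask, pair, field) {
  nr <- nrow(field@vx); nc <- ncol(field@vx)
  cc <- gridCoords(nr, nc, field@spacing, field@origin)
  col <- pmin(pmax(round(cc$x / pair@pixelSize) + 1L, 1L), ncol(mask))
  row <- pmin(pmax(round(cc$y / pair@pixelSize) + 1L, 1L), nrow(mask))
  mask[row, col, drop = FALSE]
}

#' Quiver and heat-map plots of gridded fields
#'
#' @param field a \linkS4class{VectorField2D}.
#' @param path output PNG path.
#' @param subsample plot every n-th vector (default: auto).
#' @param main plot title.
#' @return invisibly, the output path.
#' @export
plotQuiver <- function(field, path, subsample = NULL, main = "") {
  m <- fieldMagnitude(field)
  nr <- nrow(m); nc <- ncol(m)
  if (is.null(subsample)) subsample <- max(1L, floor(max(nr, nc) / 40))
  ii <- seq(1, nr, by = subsample); jj <- seq(1, nc, by = subsample)
  cc <- gridCoords(nr, nc, field@spacing, field@origin)
  sc <- 0.9 * subsample * field@spacing / max(m, na.rm = TRUE)
  grDevices::png(path, width = 800, height = 800)
  on.exit(grDevices::dev.off())
  plot(NA, xlim = range(cc$x), ylim = rev(range(cc$y)), asp = 1,
       xlab = "x (um)", ylab = "y (um)", main = main)
  x0 <- rep(cc$x[jj], each = length(ii))
  y0 <- rep(cc$y[ii], times = length(jj))
  dx <- as.vector(field@vx[ii, jj]) * sc
  dy <- as.vector(field@vy[ii, jj]) * sc
  keep <- is.finite(dx) & is.finite(dy) & (abs(dx) + abs(dy)) > 0
  graphics::arrows(x0[keep], y0[keep], x0[keep] + dx[keep],
                   y0[keep] + dy[keep], length = 0.04, col = "steelblue")
  invisible(path)
}

#' @rdname plotQuiver
#' @param z matrix to display.
#' @param spacing grid spacing in um.
#' @export
plotHeat <- function(z, spacing, path, main = "") {
  grDevices::png(path, width = 800, height = 800)
  on.exit(grDevices::dev.off())
  zz <- t(z)[, rev(seq_len(nrow(z))), drop = FALSE]  # image() orientation
  graphics::image(x = (seq_len(nrow(zz)) - 1) * spacing,
                  y = (seq_len(ncol(zz)) - 1) * spacing,
                  z = zz, col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "x (um)", ylab = "y (um)", main = main,
                  useRaster = TRUE, asp = 1)
  invisible(path)
}
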