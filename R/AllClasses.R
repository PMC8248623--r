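#' @import methods
#' @importFrom stats sd var median optimize
#' @importFrom utils head tail write.table read.table
NULL

#' Gridded 2D vector field
#'
#' Container for a regularly gridded, two-component vector field such as a
#' substrate deformation field (\code{units = "um"}) or a traction field
#' (\code{units = "Pa"}). Matrices are stored image-style: rows are y
#' (increasing downward), columns are x. \code{spacing} is the physical
#' distance between neighbouring grid points and \code{origin} the physical
#' (x, y) position of grid point \code{[1, 1]}, both in micrometres.
#'
#' @slot vx,vy numeric matrices of identical dimension; x and y components.
#' @slot spacing positive scalar, grid spacing in micrometres.
#' @slot origin numeric length-2, physical position (x, y) of element [1,1] (um).
#' @slot units character, physical unit of the components ("um" or "Pa").
#'
#' @export
setClass("VectorField2D",
  representation(vx = "matrix", vy = "matrix", spacing = "numeric",
                 origin = "numeric", units = "character"),
  prototype(spacing = 1, origin = c(0, 0), units = ""))

setValidity("VectorField2D", function(object) {
  if (!all(dim(object@vx) == dim(object@vy)))
    return("'vx' and 'vy' must have identical dimensions")
  if (length(object@spacing) != 1 || !is.finite(object@spacing) ||
      object@spacing <= 0)
    return("'spacing' must be a positive scalar")
  if (length(object@origin) != 2 || any(!is.finite(object@origin)))
    return("'origin' must be a finite length-2 vector")
  TRUE
})

#' Construct a VectorField2D
#'
#' @param vx,vy component matrices (rows = y, columns = x).
#' @param spacing grid spacing in micrometres.
#' @param origin physical (x, y) position of element [1,1] in micrometres.
#' @param units unit label for the components.
#' @return A \linkS4class{VectorField2D}.
#' @examples
#' vectorField2D(matrix(0, 4, 4), matrix(0, 4, 4), spacing = 2)
#' @export
vectorField2D <- function(vx, vy, spacing = 1, origin = c(0, 0), units = "") {
  new("VectorField2D", vx = vx, vy = vy, spacing = as.numeric(spacing),
      origin = as.numeric(origin), units = as.character(units))
}

#' Pair of substrate bead images
#'
#' Tensed (cells pulling) and relaxed (cells detached) grayscale images of
#' the fiducial-marker layer of the elastic substrate, plus the physical
#' pixel size. After drift correction both images share the same field of
#' view.
#'
#' @slot tensed,relaxed numeric intensity matrices of identical dimension.
#' @slot pixelSize pixel size in micrometres per pixel.
#'
#' @export
setClass("ImagePair",
  representation(tensed = "matrix", relaxed = "matrix", pixelSize = "numeric"))

setValidity("ImagePair", function(object) {
  if (!all(dim(object@tensed) == dim(object@relaxed)))
    return("'tensed' and 'relaxed' must have identical dimensions")
  if (length(object@pixelSize) != 1 || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    return("'pixelSize' must be a positive scalar (um/px)")
  TRUE
})

#' Construct an ImagePair
#'
#' @param tensed,relaxed grayscale intensity matrices (rows = y, columns = x).
#' @param pixelSize micrometres per pixel.
#' @return An \linkS4class{ImagePair}.
#' @export
imagePair <- function(tensed, relaxed, pixelSize = 1) {
  new("ImagePair", tensed = tensed, relaxed = relaxed,
      pixelSize = as.numeric(pixelSize))
}

#' Linearly elastic substrate description
#'
#' @slot young Young's modulus E in Pa.
#' @slot poisson Poisson's ratio, in [0, 0.5].
#' @slot thickness substrate thickness in micrometres; \code{Inf} selects the
#'   classical elastic half-space (Boussinesq) solution.
#'
#' @export
setClass("ElasticSubstrate",
  representation(young = "numeric", poisson = "numeric", thickness = "numeric"))

setValidity("ElasticSubstrate", function(object) {
  if (object@young <= 0) return("'young' must be > 0")
  if (object@poisson < 0 || object@poisson > 0.5)
    return("'poisson' must be in [0, 0.5]")
  if (object@thickness <= 0) return("'thickness' must be > 0 (or Inf)")
  TRUE
})

#' Construct an ElasticSubstrate
#'
#' @param young Young's modulus in Pa.
#' @param poisson Poisson's ratio (0 to 0.5).
#' @param thickness thickness in micrometres, \code{Inf} for a half-space.
#' @return An \linkS4class{ElasticSubstrate}.
#' @examples
#' elasticSubstrate(young = 49000, poisson = 0.5, thickness = 100)
#' @export
elasticSubstrate <- function(young, poisson = 0.5, thickness = Inf) {
  new("ElasticSubstrate", young = as.numeric(young),
      poisson = as.numeric(poisson), thickness = as.numeric(thickness))
}

#' Per-pixel symmetric 2x2 stress tensor field
#'
#' Two-dimensional (sheet) stress in N/m under the unit-thickness plane-stress
#' convention. \code{sxy} equals \code{syx} by construction. Entries outside
#' \code{mask} are \code{NA}.
#'
#' @slot sxx,syy,sxy numeric matrices of identical dimension (N/m).
#' @slot spacing grid spacing in micrometres.
#' @slot origin physical position (x, y) of element [1,1] in micrometres.
#' @slot mask logical matrix; TRUE where the tensor is defined.
#'
#' @export
setClass("StressTensorField",
  representation(sxx = "matrix", syy = "matrix", sxy = "matrix",
                 spacing = "numeric", origin = "numeric", mask = "matrix"))

setValidity("StressTensorField", function(object) {
  d <- dim(object@sxx)
  if (!all(dim(object@syy) == d) || !all(dim(object@sxy) == d) ||
      !all(dim(object@mask) == d))
    return("all component matrices and 'mask' must share dimensions")
  if (!is.logical(object@mask)) return("'mask' must be logical")
  if (object@spacing <= 0) return("'spacing' must be > 0")
  w <- object@mask & !is.na(object@mask)
  if (any(!is.finite(object@sxx[w])) || any(!is.finite(object@syy[w])) ||
      any(!is.finite(object@sxy[w])))
    return("tensor components must be finite inside the mask")
  TRUE
})

#' Construct a StressTensorField
#'
#' @param sxx,syy,sxy component matrices in N/m (rows = y, columns = x).
#' @param spacing grid spacing in micrometres.
#' @param origin physical (x, y) position of element [1,1] in micrometres.
#' @param mask logical matrix of valid pixels (default: all finite entries).
#' @return A \linkS4class{StressTensorField}.
#' @export
stressTensorField <- function(sxx, syy, sxy, spacing = 1, origin = c(0, 0),
                              mask = NULL) {
  if (is.null(mask))
    mask <- is.finite(sxx) & is.finite(syy) & is.finite(sxy)
  new("StressTensorField", sxx = sxx, syy = syy, sxy = sxy,
      spacing = as.numeric(spacing), origin = as.numeric(origin), mask = mask)
}

#' Quadrilateral finite-element grid over a pixel mask
#'
#' One bilinear quadrilateral element per masked pixel, nodes at pixel
#' corners. Node coordinates are in micrometres; \code{pixels} maps each
#' element to its (row, col) pixel in the mask's frame.
#'
#' @slot nodeX,nodeY node coordinates (um).
#' @slot elements integer matrix (nElements x 4) of node indices, ordered
#'   (x, y), (x+a, y), (x+a, y+a), (x, y+a).
#' @slot pixels integer matrix (nElements x 2) of (row, col) pixel indices.
#' @slot spacing element edge length (um).
#' @slot dim dimension of the underlying pixel grid.
#'
#' @export
setClass("FEMGrid",
  representation(nodeX = "numeric", nodeY = "numeric", elements = "matrix",
                 pixels = "matrix", spacing = "numeric", dim = "integer"))

setValidity("FEMGrid", function(object) {
  if (ncol(object@elements) != 4) return("'elements' must have 4 columns")
  if (length(object@nodeX) != length(object@nodeY))
    return("'nodeX' and 'nodeY' must have equal length")
  if (any(object@elements < 1) ||
      any(object@elements > length(object@nodeX)))
    return("element node indices out of range")
  if (any(apply(object@elements, 1, anyDuplicated) > 0))
    return("every element must reference 4 distinct nodes")
  if (object@spacing <= 0) return("'spacing' must be > 0")
  TRUE
})

## ---- accessors ----

#' @describeIn VectorField2D x component matrix
#' @param object,x a \code{VectorField2D}
#' @export
setGeneric("vx", function(object) standardGeneric("vx"))
#' @describeIn VectorField2D y component matrix
#' @export
setGeneric("vy", function(object) standardGeneric("vy"))
#' @describeIn VectorField2D grid spacing (um)
#' @export
setGeneric("spacing", function(object) standardGeneric("spacing"))
#' @describeIn VectorField2D physical origin of element [1,1] (um)
#' @export
setGeneric("origin", function(object) standardGeneric("origin"))

setMethod("vx", "VectorField2D", function(object) object@vx)
setMethod("vy", "VectorField2D", function(object) object@vy)
setMethod("spacing", "VectorField2D", function(object) object@spacing)
setMethod("origin", "VectorField2D", function(object) object@origin)
setMethod("spacing", "StressTensorField", function(object) object@spacing)
setMethod("origin", "StressTensorField", function(object) object@origin)

#' @export
setMethod("dim", "VectorField2D", function(x) dim(x@vx))
#' @export
setMethod("dim", "StressTensorField", function(x) dim(x@sxx))

#' Magnitude of a vector field
#'
#' @param object a \linkS4class{VectorField2D}
#' @return matrix of per-pixel Euclidean magnitudes.
#' @export
setGeneric("fieldMagnitude", function(object) standardGeneric("fieldMagnitude"))
setMethod("fieldMagnitude", "VectorField2D", function(object)
  sqrt(object@vx^2 + object@vy^2))

## ---- show methods ----

setMethod("show", "VectorField2D", function(object) {
  d <- dim(object@vx)
  m <- fieldMagnitude(object)
  cat(sprintf("VectorField2D: %d x %d grid, spacing %.3g um%s\n",
              d[1], d[2], object@spacing,
              if (nzchar(object@units)) paste0(", units ", object@units) else ""))
  cat(sprintf("  |v|: mean %.4g, max %.4g\n",
              mean(m, na.rm = TRUE), max(m, na.rm = TRUE)))
})

setMethod("show", "ImagePair", function(object) {
  d <- dim(object@tensed)
  cat(sprintf("ImagePair: %d x %d px, pixel size %.3g um/px\n",
              d[1], d[2], object@pixelSize))
})

setMethod("show", "ElasticSubstrate", function(object) {
  cat(sprintf("ElasticSubstrate: E = %.4g Pa, nu = %.3g, h = %s\n",
              object@young, object@poisson,
              if (is.infinite(object@thickness)) "Inf (half-space)"
              else sprintf("%.4g um", object@thickness)))
})

setMethod("show", "StressTensorField", function(object) {
  d <- dim(object@sxx)
  mn <- meanNormalStress(object)
  cat(sprintf("StressTensorField: %d x %d grid, spacing %.3g um, %d masked px\n",
              d[1], d[2], object@spacing, sum(object@mask)))
  cat(sprintf("  mean normal stress: %.4g N/m\n", mean(mn[object@mask])))
})

setMethod("show", "FEMGrid", function(object) {
  cat(sprintf("FEMGrid: %d elements, %d nodes, spacing %.3g um\n",
              nrow(object@elements), length(object@nodeX), object@spacing))
})
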