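# Monolayer Stress Microscopy: the 2D internal stress tensor of a cell
# sheet is recovered by loading a plane-stress finite-element model of the
# sheet with the negated measured tractions and reading off the element
# stresses. The sheet's Young's modulus cancels exactly from the
# traction-to-stress map (it scales K and the constitutive law inversely),
# and its Poisson's ratio has only a weak influence; both are fixed to the
# conventional E = 1 Pa, nu = 0.5 by default.
#
# Rigid-body indeterminacy is removed not by pinning nodes but by appending
# whole-system zero-translation and zero-rotation conditions
#   sum(dx) = 0,  sum(dy) = 0,  sum(dx*ry - dy*rx) = 0
# (r measured from the grid's centre of mass) to K d = f and solving the
# combined system in the least-squares sense; with a balanced load this is
# solved exactly through its Lagrange (KKT) optimality system.

#' @importFrom Matrix sparseMatrix solve t Diagonal
NULL

#' Build a quadrilateral FEM grid over a pixel mask
#'
#' One bilinear quadrilateral element per masked pixel, with nodes at pixel
#' corners. Interior holes are filled (with a warning); a disconnected mask
#' is an error because the rigid-body constraints assume one connected body.
#'
#' @param mask logical matrix (rows = y, cols = x) of pixels to cover.
#' @param spacing pixel edge length in um.
#' @return A \linkS4class{FEMGrid}.
#' @examples
#' g <- buildFEMGrid(matrix(TRUE, 3, 4), spacing = 1)  # 12 elements, 20 nodes
#' @export
buildFEMGrid <- function(mask, spacing) {
  stopifnot(is.matrix(mask), spacing > 0)
  mask <- mask & !is.na(mask)
  if (!any(mask)) stop("mask is empty")
  filled <- fillHoles(mask)
  if (any(filled & !mask)) {
    warning(sprintf("mask had %d interior hole pixel(s); filled",
                    sum(filled & !mask)))
    mask <- filled
  }
  ncomp <- connectedComponents(mask)
  if (ncomp > 1)
    stop(sprintf("mask has %d disconnected components; expected 1", ncomp))
  nr <- nrow(mask); nc <- ncol(mask)
  pix <- which(mask, arr.ind = TRUE)           # (row, col) per element
  ## corner nodes live on an (nr+1) x (nc+1) grid; corner (i, j) has
  ## physical position x = (j-1)*a, y = (i-1)*a
  cornerId <- function(i, j) (j - 1L) * (nr + 1L) + i
  r <- pix[, 1]; cl <- pix[, 2]
  elemCorners <- cbind(cornerId(r, cl),        # (x,   y)
                       cornerId(r, cl + 1L),   # (x+a, y)
                       cornerId(r + 1L, cl + 1L),  # (x+a, y+a)
                       cornerId(r + 1L, cl))   # (x,   y+a)
  used <- sort(unique(as.vector(elemCorners)))
  remap <- integer((nr + 1L) * (nc + 1L))
  remap[used] <- seq_along(used)
  elements <- matrix(remap[elemCorners], ncol = 4)
  ui <- (used - 1L) %% (nr + 1L) + 1L
  uj <- (used - 1L) %/% (nr + 1L) + 1L
  new("FEMGrid",
      nodeX = (uj - 1) * spacing, nodeY = (ui - 1) * spacing,
      elements = elements, pixels = unname(cbind(r, cl)),
      spacing = as.numeric(spacing), dim = c(nr, nc))
}

#' Nodal force vector from a traction field
#'
#' Each element (pixel) contributes the force \eqn{-t \, a^2} (traction at
#' the pixel centre times pixel area), shared equally among its four corner
#' nodes. Forces are in newtons (spacing converted from um to m).
#'
#' @param t traction \linkS4class{VectorField2D} in Pa, on the pixel grid of
#'   the mask the grid was built from.
#' @param grid a \linkS4class{FEMGrid}.
#' @return numeric vector of length 2 * nNodes, interleaved as
#'   (fx1, fy1, fx2, fy2, ...).
#' @export
nodalForces <- function(t, grid) {
  stopifnot(is(t, "VectorField2D"), is(grid, "FEMGrid"))
  d <- dim(t@vx)
  if (max(grid@pixels[, 1]) > d[1] || max(grid@pixels[, 2]) > d[2])
    stop("FEM grid extends outside the traction field")
  aSI <- grid@spacing * 1e-6
  idx <- grid@pixels
  fxE <- -t@vx[idx] * aSI^2
  fyE <- -t@vy[idx] * aSI^2
  n <- length(grid@nodeX)
  f <- numeric(2L * n)
  for (k in 1:4) {
    nd <- grid@elements[, k]
    fx <- rowsum(fxE / 4, nd)
    fy <- rowsum(fyE / 4, nd)
    who <- as.integer(rownames(fx))
    f[2L * who - 1L] <- f[2L * who - 1L] + fx[, 1]
    f[2L * who] <- f[2L * who] + fy[, 1]
  }
  f
}

#' Balance net force and net torque of a nodal force vector
#'
#' Removes the net force by subtracting the mean force vector from every
#' node, then nulls the net torque about the grid's centre of mass by
#' rotating every force vector by the closed-form angle \eqn{\alpha} with
#' \eqn{\tan\alpha = -T_0 / D_0}, where \eqn{T_0 = \sum r \times f} and
#' \eqn{D_0 = \sum r \cdot f}. The angle is typically well below 5 degrees.
#'
#' @param f nodal force vector (interleaved x, y), in N.
#' @param nodeX,nodeY node coordinates (um).
#' @return list with the balanced vector \code{f} and the rotation angle
#'   \code{alpha} in radians.
#' @export
balanceForces <- function(f, nodeX, nodeY) {
  n <- length(f) / 2
  if (n < 2) stop("need at least 2 nodes")
  fx <- f[seq(1, 2 * n, by = 2)]
  fy <- f[seq(2, 2 * n, by = 2)]
  fx <- fx - mean(fx)
  fy <- fy - mean(fy)
  rx <- nodeX - mean(nodeX)
  ry <- nodeY - mean(nodeY)
  T0 <- sum(rx * fy - ry * fx)
  D0 <- sum(rx * fx + ry * fy)
  ## net torque after rotating all forces by alpha is
  ## T0*cos(alpha) + D0*sin(alpha); it vanishes for alpha = atan(-T0/D0)
  ## (mod pi). Take the principal (small-angle) root.
  alpha <- if (T0 == 0) 0 else if (D0 == 0) -sign(T0) * pi / 2
           else atan(-T0 / D0)
  ca <- cos(alpha); sa <- sin(alpha)
  fxr <- ca * fx - sa * fy
  fyr <- sa * fx + ca * fy
  out <- numeric(2 * n)
  out[seq(1, 2 * n, by = 2)] <- fxr
  out[seq(2, 2 * n, by = 2)] <- fyr
  list(f = out, alpha = alpha)
}

## 8x8 plane-stress stiffness matrix of a square bilinear element with edge
## a (m), unit thickness, 2x2 Gauss quadrature. Dof order (x1,y1,...,x4,y4)
## for corner order (0,0), (a,0), (a,a), (0,a) in (x, y).
elementStiffness <- function(a, E, nu) {
  D <- E / (1 - nu^2) * matrix(c(1, nu, 0, nu, 1, 0, 0, 0, (1 - nu) / 2), 3, 3)
  gp <- 0.5 + c(-1, 1) / (2 * sqrt(3))
  Ke <- matrix(0, 8, 8)
  for (xi in gp) for (eta in gp) {
    ## shape functions N1=(1-xi)(1-eta), N2=xi(1-eta), N3=xi*eta, N4=(1-xi)eta
    dNdx <- c(-(1 - eta), (1 - eta), eta, -eta) / a
    dNdy <- c(-(1 - xi), -xi, xi, (1 - xi)) / a
    B <- matrix(0, 3, 8)
    B[1, seq(1, 8, 2)] <- dNdx
    B[2, seq(2, 8, 2)] <- dNdy
    B[3, seq(1, 8, 2)] <- dNdy
    B[3, seq(2, 8, 2)] <- dNdx
    Ke <- Ke + t(B) %*% D %*% B * (a^2 / 4)
  }
  Ke
}

#' Assemble the global sparse stiffness matrix
#'
#' Plane-stress bilinear-quadrilateral stiffness over all elements of the
#' grid (unit thickness; element edge converted from um to m).
#'
#' @param grid a \linkS4class{FEMGrid}.
#' @param E,nu sheet elastic constants.
#' @return sparse symmetric matrix of dimension 2 nNodes.
#' @export
assembleStiffness <- function(grid, E = 1, nu = 0.5) {
  a <- grid@spacing * 1e-6
  Ke <- elementStiffness(a, E, nu)
  ne <- nrow(grid@elements)
  dof <- matrix(0L, ne, 8)
  dof[, seq(1, 8, 2)] <- 2L * grid@elements - 1L
  dof[, seq(2, 8, 2)] <- 2L * grid@elements
  ii <- dof[, rep(1:8, each = 8)]
  jj <- dof[, rep(1:8, times = 8)]
  xx <- rep(as.vector(t(Ke)), each = ne)  # Ke[p, q] pairs with (i=p, j=q)
  n2 <- 2L * length(grid@nodeX)
  Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj), x = xx,
                       dims = c(n2, n2))
}

#' Solve the constrained FEM system for nodal displacements
#'
#' Solves \eqn{K d = f} together with the whole-system conditions
#' \eqn{\sum d_x = 0}, \eqn{\sum d_y = 0} and
#' \eqn{\sum (d_x r_y - d_y r_x) = 0} (r from the centre of mass of the
#' nodes). The combined least-squares problem is solved exactly through its
#' Lagrange optimality (KKT) system; with a balanced load the constraint
#' residuals vanish to solver precision. \code{method = "pin"} instead pins
#' one node fully and the cross-axis displacement of a second node on the
#' same row, the classical alternative; the two schemes differ only by a
#' rigid-body motion and give identical stresses.
#'
#' @param K sparse stiffness matrix from [assembleStiffness()].
#' @param f balanced nodal force vector (N).
#' @param grid the \linkS4class{FEMGrid}.
#' @param method "leastsquares" (default) or "pin".
#' @return numeric displacement vector d (length 2 * nNodes).
#' @export
solveDisplacements <- function(K, f, grid, method = c("leastsquares", "pin")) {
  method <- match.arg(method)
  n <- length(grid@nodeX)
  rx <- grid@nodeX - mean(grid@nodeX)
  ry <- grid@nodeY - mean(grid@nodeY)
  if (method == "leastsquares") {
    ## The three constraint vectors span exactly the rigid-body null space
    ## of K (two translations and the linearized rotation (-ry, rx)), and a
    ## balanced load lies in range(K). The least-squares solution of the
    ## combined system is therefore any particular solution of K d = f with
    ## its rigid-body component removed so that the three constraints hold
    ## exactly. Solve the SPD pinned system by sparse Cholesky, then project.
    d <- pinnedSolve(K, f, grid)
    e1 <- rep(c(1, 0), n)
    e2 <- rep(c(0, 1), n)
    e3 <- as.vector(rbind(-ry, rx))     # d of a unit linearized rotation
    B <- cbind(e1, e2, e3)
    coef <- solve(crossprod(B), crossprod(B, d))
    d <- d - as.numeric(B %*% coef)
  } else {
    d <- pinnedSolve(K, f, grid)
  }
  d
}

## particular solution of K d = f: pin the node nearest the centre of mass
## (both dofs) and, to block rotation, the y-displacement of the farthest
## node on the same row; solve the remaining SPD system by sparse Cholesky
pinnedSolve <- function(K, f, grid) {
  n <- length(grid@nodeX)
  rx <- grid@nodeX - mean(grid@nodeX)
  ry <- grid@nodeY - mean(grid@nodeY)
  i0 <- which.min(rx^2 + ry^2)
  sameRow <- which(abs(grid@nodeY - grid@nodeY[i0]) < grid@spacing / 2)
  i1 <- sameRow[which.max(abs(grid@nodeX[sameRow] - grid@nodeX[i0]))]
  if (i1 == i0) stop("cannot find a second pin node")
  fixed <- c(2L * i0 - 1L, 2L * i0, 2L * i1)
  free <- setdiff(seq_len(2 * n), fixed)
  Kff <- Matrix::forceSymmetric(K[free, free])
  d <- numeric(2 * n)
  d[free] <- as.numeric(Matrix::solve(Matrix::Cholesky(Kff), f[free]))
  d
}

#' Strain and stress fields from nodal displacements
#'
#' Evaluates the shape-function derivatives of each bilinear element at the
#' element centre (equal to the 2x2 Gauss average) to obtain the strain
#' tensor per pixel, then applies the plane-stress constitutive law
#' \deqn{(\sigma_{11}, \sigma_{22}, \sigma_{12}) = \frac{E}{1-\nu^2}
#'   \begin{pmatrix} 1 & \nu & 0 \\ \nu & 1 & 0 \\ 0 & 0 & 1-\nu
#'   \end{pmatrix} (\epsilon_{11}, \epsilon_{22}, \epsilon_{12}).}
#' Under the unit-thickness convention the result is the 2D sheet stress in
#' N/m.
#'
#' @param d displacement vector from [solveDisplacements()].
#' @param grid the \linkS4class{FEMGrid}.
#' @param E,nu sheet elastic constants (defaults 1 Pa and 0.5).
#' @return list with \code{strain} (list of matrices e11, e22, e12) and
#'   \code{stress} (a \linkS4class{StressTensorField}), both on the pixel
#'   grid of the original mask.
#' @export
stressFromDisplacements <- function(d, grid, E = 1, nu = 0.5) {
  a <- grid@spacing * 1e-6
  el <- grid@elements
  ux <- matrix(d[2 * el - 1], ncol = 4)
  uy <- matrix(d[2 * el], ncol = 4)
  ## dN/dx, dN/dy at element centre (xi = eta = 1/2)
  dNdx <- c(-0.5, 0.5, 0.5, -0.5) / a
  dNdy <- c(-0.5, -0.5, 0.5, 0.5) / a
  e11 <- as.vector(ux %*% dNdx)
  e22 <- as.vector(uy %*% dNdy)
  e12 <- 0.5 * as.vector(ux %*% dNdy + uy %*% dNdx)
  fac <- E / (1 - nu^2)
  s11 <- fac * (e11 + nu * e22)
  s22 <- fac * (nu * e11 + e22)
  s12 <- fac * (1 - nu) * e12
  toGrid <- function(v) {
    m <- matrix(NA_real_, grid@dim[1], grid@dim[2])
    m[grid@pixels] <- v
    m
  }
  mask <- matrix(FALSE, grid@dim[1], grid@dim[2])
  mask[grid@pixels] <- TRUE
  stress <- stressTensorField(toGrid(s11), toGrid(s22), toGrid(s12),
                              spacing = grid@spacing, mask = mask)
  list(strain = list(e11 = toGrid(e11), e22 = toGrid(e22), e12 = toGrid(e12)),
       stress = stress)
}

#' Monolayer stress recovery from a traction field
#'
#' Convenience wrapper chaining [buildFEMGrid()], [nodalForces()],
#' [balanceForces()], stiffness assembly, [solveDisplacements()] and
#' [stressFromDisplacements()].
#'
#' @param t traction \linkS4class{VectorField2D} (Pa).
#' @param mask logical matrix: the traction area / FEM-grid support.
#' @param spacing pixel size in um (defaults to the traction grid spacing).
#' @param E,nu sheet elastic constants; the stress result is independent of
#'   E and only weakly sensitive to nu.
#' @param method constraint scheme, see [solveDisplacements()].
#' @return list with \code{stress} (\linkS4class{StressTensorField}),
#'   \code{strain}, \code{displacements}, \code{grid}, and the torque-
#'   balancing rotation angle \code{alpha} (rad).
#' @export
monolayerStress <- function(t, mask, spacing = NULL, E = 1, nu = 0.5,
                            method = c("leastsquares", "pin")) {
  method <- match.arg(method)
  if (is.null(spacing)) spacing <- t@spacing
  grid <- buildFEMGrid(mask, spacing)
  f <- nodalForces(t, grid)
  bal <- balanceForces(f, grid@nodeX, grid@nodeY)
  K <- assembleStiffness(grid, E = E, nu = nu)
  d <- solveDisplacements(K, bal$f, grid, method = method)
  out <- stressFromDisplacements(d, grid, E = E, nu = nu)
  list(stress = out$stress, strain = out$strain, displacements = d,
       grid = grid, alpha = bal$alpha)
}
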