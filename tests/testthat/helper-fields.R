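# Shared fixture builders. Everything is generated in code at test time.

## coordinate matrices (um) for an n x n grid at unit spacing
coordMats <- function(n, spacing = 1) {
  cc <- monolayerTFM:::gridCoords(n, n, spacing)
  list(X = outer(rep(1, n), cc$x), Y = outer(cc$y, rep(1, n)))
}

## smooth, globally balanced traction field: two opposing Gaussian force
## blobs (a contractile dipole along x)
dipoleTraction <- function(n = 64, spacing = 1, sep = 20, width = 5,
                           amp = 100) {
  cm <- coordMats(n, spacing)
  ctr <- (n - 1) * spacing / 2
  g <- function(x0) amp * exp(-(((cm$X - x0)^2 + (cm$Y - ctr)^2) /
                                  (2 * width^2)))
  tx <- g(ctr - sep / 2) - g(ctr + sep / 2)   # blobs pull toward each other
  vectorField2D(tx, matrix(0, n, n), spacing = spacing, units = "Pa")
}

## small synthetic square-patch spec for fast end-to-end runs
smallSpec <- function(...) {
  syntheticSpec(fieldSize = 128, spacing = 1, patchWidth = 50,
                thickness = 100, ...)
}

## brute-force epicenter: minimize the summed squared force-line moments by
## Nelder-Mead from a coarse grid start (independent of the linear solve)
bruteForceEpicenter <- function(t, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(vx(t)), ncol(vx(t)))
  idx <- which(mask, arr.ind = TRUE)
  cc <- monolayerTFM:::gridCoords(nrow(vx(t)), ncol(vx(t)), spacing(t),
                                  origin(t))
  xi <- cc$x[idx[, 2]]; yi <- cc$y[idx[, 1]]
  Fx <- vx(t)[idx]; Fy <- vy(t)[idx]
  obj <- function(p) sum((Fx * (p[2] - yi) - Fy * (p[1] - xi))^2)
  grid <- as.matrix(expand.grid(x = seq(min(xi), max(xi), length.out = 15),
                                y = seq(min(yi), max(yi), length.out = 15)))
  v <- apply(grid, 1, obj)
  start <- grid[which.min(v), ]
  stats::optim(start, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))$par
}
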