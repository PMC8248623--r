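# FEM grid construction, force balancing, the constrained solve and the
# strain/stress recovery.

test_that("grid construction counts elements and nodes correctly", {
  g1 <- buildFEMGrid(matrix(TRUE, 1, 1), 1)
  expect_equal(nrow(g1@elements), 1)
  expect_equal(length(g1@nodeX), 4)
  g2 <- buildFEMGrid(matrix(TRUE, 3, 5), 2)
  expect_equal(nrow(g2@elements), 15)
  expect_equal(length(g2@nodeX), 4 * 6)
})

test_that("interior holes are filled with a warning; disconnection errors", {
  m <- matrix(TRUE, 7, 7)
  m[4, 4] <- FALSE
  expect_warning(g <- buildFEMGrid(m, 1), "hole")
  expect_equal(nrow(g@elements), 49)
  m2 <- matrix(FALSE, 5, 9)
  m2[2:4, 1:3] <- TRUE
  m2[2:4, 7:9] <- TRUE
  expect_error(buildFEMGrid(m2, 1), "2 disconnected")
})

test_that("nodal forces conserve the total applied traction", {
  n <- 6
  tr <- vectorField2D(matrix(10, n, n), matrix(-4, n, n), spacing = 2,
                      units = "Pa")
  g <- buildFEMGrid(matrix(TRUE, n, n), 2)
  f <- nodalForces(tr, g)
  a <- 2e-6
  expect_equal(sum(f[seq(1, length(f), 2)]), -10 * n * n * a^2,
               tolerance = 1e-12)
  expect_equal(sum(f[seq(2, length(f), 2)]), 4 * n * n * a^2,
               tolerance = 1e-12)
  zero <- vectorField2D(matrix(0, n, n), matrix(0, n, n), spacing = 2)
  expect_equal(max(abs(nodalForces(zero, g))), 0)
  expect_error(nodalForces(tr, buildFEMGrid(matrix(TRUE, 10, 10), 2)),
               "outside")
})

test_that("synthetic square tractions are balanced before any correction", {
  sp <- smallSpec()
  tr <- tractionFromStress(makeSquareStress(sp))
  g <- buildFEMGrid(matrix(TRUE, 128, 128), 1)
  f <- nodalForces(tr, g)
  fx <- f[seq(1, length(f), 2)]; fy <- f[seq(2, length(f), 2)]
  expect_lt(abs(sum(fx)) / sum(abs(fx)), 1e-10)
  torque <- sum(g@nodeX * fy - g@nodeY * fx)
  expect_lt(abs(torque) / sum(abs(g@nodeX * fy)), 1e-10)
})

test_that("force balancing removes constants exactly and nulls couples", {
  set.seed(3)
  nx <- runif(50, 0, 10); ny <- runif(50, 0, 10)
  f0 <- rnorm(100)
  b0 <- balanceForces(f0, nx, ny)
  ## balanced input (already zero-mean, torque nulled) is a fixed point
  b1 <- balanceForces(b0$f, nx, ny)
  expect_equal(b1$f, b0$f, tolerance = 1e-12)
  expect_equal(b1$alpha, 0, tolerance = 1e-9)
  ## adding a constant vector to every node changes nothing
  fc <- f0 + rep(c(0.7, -1.3), 50)
  bc <- balanceForces(fc, nx, ny)
  expect_equal(bc$f, b0$f, tolerance = 1e-12)
  ## pure couple: tangential ring forces; closed-form angle nulls the torque
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  cx <- cos(th); cy <- sin(th)
  fr <- as.vector(rbind(-cy, cx))          # tangential
  br <- balanceForces(fr, cx, cy)
  fx <- br$f[seq(1, 24, 2)]; fy <- br$f[seq(2, 24, 2)]
  expect_lt(abs(sum(cx * fy - cy * fx)), 1e-12)
  expect_equal(abs(br$alpha), pi / 2)
})

test_that("whole-system constraints hold to 1e-9 of the displacement norm", {
  sp <- smallSpec()
  res <- squarePatchExperiment(sp, margin = 4)
  g <- buildFEMGrid(res$femMask, 1)
  d <- monolayerStress(res$tractionRecovered, res$femMask)$displacements
  dx <- d[seq(1, length(d), 2)]; dy <- d[seq(2, length(d), 2)]
  rx <- g@nodeX - mean(g@nodeX); ry <- g@nodeY - mean(g@nodeY)
  nrm <- sqrt(sum(d^2))
  expect_lt(abs(sum(dx)) / nrm, 1e-9)
  expect_lt(abs(sum(dy)) / nrm, 1e-9)
  expect_lt(abs(sum(dx * ry - dy * rx)) / (nrm * max(abs(c(rx, ry)))), 1e-9)
})

test_that("zero forces give zero displacements", {
  g <- buildFEMGrid(matrix(TRUE, 5, 5), 1)
  K <- assembleStiffness(g)
  d <- solveDisplacements(K, numeric(2 * length(g@nodeX)), g)
  expect_equal(max(abs(d)), 0, tolerance = 1e-15)
})

test_that("uniform inward edge load reproduces uniform biaxial contraction", {
  ## plane-stress plate, uniform compressive edge traction p per length:
  ## sigma_xx = sigma_yy = -p, displacement u = -p(1-nu)/E * (r - r_c)
  n <- 20; a <- 1e-6; E <- 1; nu <- 0.5; p <- 1e-3   # N/m edge load
  g <- buildFEMGrid(matrix(TRUE, n, n), 1)
  K <- assembleStiffness(g, E, nu)
  f <- numeric(2 * length(g@nodeX))
  xs <- g@nodeX; ys <- g@nodeY
  L <- n * 1  # um
  onEdge <- function(v, lim) abs(v - lim) < 1e-9
  for (i in seq_along(xs)) {
    if (onEdge(xs[i], 0))
      f[2 * i - 1] <- f[2 * i - 1] + p * a *
        (if (onEdge(ys[i], 0) || onEdge(ys[i], L)) 0.5 else 1)
    if (onEdge(xs[i], L))
      f[2 * i - 1] <- f[2 * i - 1] - p * a *
        (if (onEdge(ys[i], 0) || onEdge(ys[i], L)) 0.5 else 1)
    if (onEdge(ys[i], 0))
      f[2 * i] <- f[2 * i] + p * a *
        (if (onEdge(xs[i], 0) || onEdge(xs[i], L)) 0.5 else 1)
    if (onEdge(ys[i], L))
      f[2 * i] <- f[2 * i] - p * a *
        (if (onEdge(xs[i], 0) || onEdge(xs[i], L)) 0.5 else 1)
  }
  d <- solveDisplacements(K, f, g)
  out <- stressFromDisplacements(d, g, E, nu)
  inn <- 5:16
  expect_equal(mean(out$stress@sxx[inn, inn]), -p, tolerance = 0.01)
  expect_equal(mean(out$stress@syy[inn, inn]), -p, tolerance = 0.01)
  expect_lt(max(abs(out$stress@sxy[inn, inn])), 0.01 * p)
  ## analytic displacement: pure radial contraction about the plate centre
  eps <- -p * (1 - nu) / E           # uniform biaxial strain
  dx <- d[seq(1, length(d), 2)]
  want <- eps * (xs - mean(xs)) * 1e-6   # node coords um -> m
  off <- abs(xs - mean(xs)) > 3
  expect_lt(max(abs(dx[off] - want[off]) / max(abs(want))), 0.01)
})

test_that("the stress map is invariant to the sheet Young's modulus", {
  sp <- smallSpec()
  res <- squarePatchExperiment(sp, margin = 4)
  tr <- res$tractionRecovered
  s1 <- monolayerStress(tr, res$femMask, E = 0.1)$stress
  s2 <- monolayerStress(tr, res$femMask, E = 1)$stress
  s3 <- monolayerStress(tr, res$femMask, E = 10)$stress
  m <- s1@mask
  expect_equal(s1@sxx[m], s2@sxx[m], tolerance = 1e-12)
  expect_equal(s3@syy[m], s2@syy[m], tolerance = 1e-12)
})

test_that("mean normal stress is insensitive to the sheet Poisson ratio", {
  sp <- smallSpec()
  res <- squarePatchExperiment(sp, margin = 4)
  tr <- res$tractionRecovered
  mA <- meanNormalStress(monolayerStress(tr, res$femMask, nu = 0.5)$stress)
  mB <- meanNormalStress(monolayerStress(tr, res$femMask, nu = 0.3)$stress)
  inP <- res$patchMask
  expect_equal(mean(mB[inP]) / mean(mA[inP]), 1, tolerance = 0.03)
})

test_that("least-squares and pin-node constraint schemes agree on stresses", {
  sp <- smallSpec()
  res <- squarePatchExperiment(sp, margin = 4)
  tr <- res$tractionRecovered
  sL <- monolayerStress(tr, res$femMask, method = "leastsquares")$stress
  sP <- monolayerStress(tr, res$femMask, method = "pin")$stress
  m <- sL@mask
  sc <- max(abs(sL@sxx[m]))
  expect_lt(max(abs(sL@sxx[m] - sP@sxx[m])), 1e-6 * sc)
  expect_lt(max(abs(sL@syy[m] - sP@syy[m])), 1e-6 * sc)
  expect_lt(max(abs(sL@sxy[m] - sP@sxy[m])), 1e-6 * sc)
})

test_that("rigid translation produces zero strain and stress", {
  g <- buildFEMGrid(matrix(TRUE, 6, 6), 1)
  d <- rep(c(3e-6, -2e-6), length(g@nodeX))
  out <- stressFromDisplacements(d, g)
  ## zero up to cancellation roundoff of (translation) x (1/element size)
  expect_lt(max(abs(out$stress@sxx), abs(out$stress@syy),
                abs(out$stress@sxy), na.rm = TRUE), 1e-12)
})

test_that("plane-stress law maps strain to stress as specified", {
  ## eps11 = e0, eps22 = eps12 = 0, E = 1, nu = 0.5:
  ## sigma11 = 4/3 e0, sigma22 = 2/3 e0, sigma12 = 0
  n <- 4; e0 <- 1e-3
  g <- buildFEMGrid(matrix(TRUE, n, n), 1)
  d <- numeric(2 * length(g@nodeX))
  d[seq(1, length(d), 2)] <- e0 * g@nodeX * 1e-6  # ux = e0 * x
  out <- stressFromDisplacements(d, g, E = 1, nu = 0.5)
  expect_equal(mean(out$stress@sxx, na.rm = TRUE), 4 / 3 * e0,
               tolerance = 1e-12)
  expect_equal(mean(out$stress@syy, na.rm = TRUE), 2 / 3 * e0,
               tolerance = 1e-12)
  expect_lt(max(abs(out$stress@sxy), na.rm = TRUE), 1e-18)
  expect_equal(mean(out$strain$e11, na.rm = TRUE), e0, tolerance = 1e-12)
})

test_that("recovered stress divergence reproduces the applied traction", {
  ## smooth balanced traction; on the interior, div(sigma) ~ t
  n <- 64
  tr <- dipoleTraction(n, amp = 50)
  msm <- monolayerStress(tr, matrix(TRUE, n, n), spacing = 1)
  s <- msm$stress
  a <- 1e-6
  ddx <- function(m) (m[, -(1:2)] - m[, 1:(ncol(m) - 2)]) / (2 * a)
  ddy <- function(m) (m[-(1:2), ] - m[1:(nrow(m) - 2), ]) / (2 * a)
  divx <- ddx(s@sxx)[2:(n - 1), ] + ddy(s@sxy)[, 2:(n - 1)]
  txi <- vx(tr)[2:(n - 1), 2:(n - 1)]
  expect_lt(sqrt(mean((divx - txi)^2)) / max(abs(txi)), 0.05)
})

test_that("expansion scan rises to a single maximum then declines", {
  sp <- smallSpec()
  sc <- scanExpansion(sp, margins = seq(0, 12, by = 2))
  r <- sc$recovery
  i <- which.max(r)
  expect_gt(i, 1)                       # strictly rises first
  expect_lt(i, length(r))               # and declines after the maximum
  expect_true(all(diff(r[1:i]) > 0))
  expect_true(all(diff(r[i:length(r)]) < 0))
  ## decline past the optimum is slow compared to the initial rise
  expect_gt(r[length(r)], 0.9 * max(r))
})
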