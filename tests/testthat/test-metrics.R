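# Scalar metrics: strain energy, contractility, stress scalars, line tension.

test_that("strain energy matches the closed form and the Parseval oracle", {
  n <- 32
  z <- matrix(0, n, n)
  expect_equal(strainEnergy(vectorField2D(z, z, 1),
                            vectorField2D(z, z, 1)), 0)
  ## uniform parallel u and t over an area A: U = 1/2 |u||t| A
  u0 <- 2; t0 <- 50; a <- 2
  u <- vectorField2D(matrix(u0, n, n), z, spacing = a)
  t <- vectorField2D(matrix(t0, n, n), z, spacing = a)
  A <- n * n * (a * 1e-6)^2
  expect_equal(strainEnergy(u, t), 0.5 * (u0 * 1e-6) * t0 * A,
               tolerance = 1e-12)
  ## mismatched grids error
  expect_error(strainEnergy(u, vectorField2D(matrix(1, 8, 8),
                                             matrix(0, 8, 8), a)), "grid")
  ## Parseval: full-area dot product evaluated in Fourier space
  sp <- smallSpec()
  tr <- tractionFromStress(makeSquareStress(sp))
  uu <- deformationFromTraction(tr, sp$substrate)
  direct <- strainEnergy(uu, tr)
  N2 <- prod(dim(vx(uu)))
  fdot <- (sum(Re(fft(vx(uu)) * Conj(fft(vx(tr))))) +
           sum(Re(fft(vy(uu)) * Conj(fft(vy(tr)))))) / N2
  parseval <- 0.5 * fdot * 1e-6 * (sp$spacing * 1e-6)^2
  expect_equal(direct, parseval, tolerance = 0.01)
})

test_that("contractility sign convention and epicenter are correct", {
  n <- 41
  tx <- matrix(0, n, n); ty <- matrix(0, n, n)
  ## two opposing point tractions pulling toward their midpoint (col 21)
  tx[21, 11] <- 100; tx[21, 31] <- -100
  t <- vectorField2D(tx, ty, spacing = 1, units = "Pa")
  co <- contractility(t)
  F <- 100 * (1e-6)^2
  expect_equal(unname(co$epicenter["y"]), 20, tolerance = 1e-6)
  expect_equal(unname(co$epicenter["x"]), 20, tolerance = 1e-6)
  expect_equal(co$contractility, 2 * F, tolerance = 1e-9)
  ## reversed (pushing outward): C = -2F
  t2 <- vectorField2D(-tx, ty, spacing = 1, units = "Pa")
  expect_equal(contractility(t2)$contractility, -2 * F, tolerance = 1e-9)
})

test_that("epicenter solve agrees with a brute-force minimizer", {
  set.seed(8)
  n <- 41
  tx <- matrix(0, n, n); ty <- matrix(0, n, n)
  ## point forces aimed exactly at (14, 26), random magnitudes
  tgt <- c(14, 26)
  for (i in 1:25) {
    r <- c(sample(n, 1), sample(n, 1))
    v <- tgt - c(r[2] - 1, r[1] - 1)
    if (all(v == 0)) next
    v <- v / sqrt(sum(v^2)) * runif(1, 10, 100)
    tx[r[1], r[2]] <- tx[r[1], r[2]] + v[1]
    ty[r[1], r[2]] <- ty[r[1], r[2]] + v[2]
  }
  t <- vectorField2D(tx, ty, spacing = 1, units = "Pa")
  co <- contractility(t)
  bf <- bruteForceEpicenter(t)
  expect_equal(unname(co$epicenter), unname(bf), tolerance = 1e-3)
  ## all forces point at the epicenter: C equals the summed magnitudes
  sumF <- sum(sqrt(tx^2 + ty^2)) * (1e-6)^2
  expect_equal(co$contractility, sumF, tolerance = 1e-6)
})

test_that("a force-free field has no epicenter", {
  n <- 21
  t <- vectorField2D(matrix(0, n, n), matrix(0, n, n), spacing = 1)
  expect_error(contractility(t), "degenerate")
})

test_that("stress scalars: isotropic, pure shear, and empty masks", {
  n <- 8
  iso <- stressTensorField(matrix(2, n, n), matrix(2, n, n),
                           matrix(0, n, n), spacing = 1)
  sc <- stressScalars(iso)
  expect_equal(sc$avgMaxNormalStress, 2)
  expect_equal(sc$avgMaxShearStress, 0)
  expect_equal(sc$avgMeanNormalStress, 2)
  expect_equal(sc$cvNormalStress, 0)
  sh <- stressTensorField(matrix(0, n, n), matrix(0, n, n),
                          matrix(3, n, n), spacing = 1)
  sc2 <- stressScalars(sh)
  expect_equal(sc2$avgMaxNormalStress, 3)   # eigenvalues +/- s
  expect_equal(sc2$avgMaxShearStress, 3)
  expect_error(stressScalars(iso, matrix(FALSE, n, n)), "empty")
})

test_that("line tension on canonical stress states", {
  n <- 21
  iso <- stressTensorField(matrix(5, n, n), matrix(5, n, n),
                           matrix(0, n, n), spacing = 1)
  b <- list(cbind(x = c(4, 16), y = c(4, 16)))   # oblique segment
  lt <- lineTension(iso, b)
  expect_equal(lt$avgNormalLineTension, 5, tolerance = 1e-12)
  expect_equal(lt$avgShearLineTension, 0, tolerance = 1e-12)
  expect_equal(lt$avgLineTension, 5, tolerance = 1e-12)
  ## uniaxial sigma_xx = s, boundary along y: tension fully normal, = s
  uni <- stressTensorField(matrix(7, n, n), matrix(0, n, n),
                           matrix(0, n, n), spacing = 1)
  by <- list(cbind(x = c(10, 10), y = c(3, 17)))
  lty <- lineTension(uni, by)
  expect_equal(lty$avgLineTension, 7, tolerance = 1e-12)
  expect_equal(abs(lty$avgNormalLineTension), 7, tolerance = 1e-12)
  expect_equal(lty$avgShearLineTension, 0, tolerance = 1e-12)
  ## reversing vertex order flips n and T together: magnitudes unchanged
  ## and the normal component (tension vs compression) keeps its sign
  rev <- lineTension(uni, list(by[[1]][2:1, ]))
  expect_equal(rev$avgLineTension, lty$avgLineTension)
  expect_equal(rev$avgNormalLineTension, lty$avgNormalLineTension)
  expect_equal(rev$avgShearLineTension, lty$avgShearLineTension)
  ## |T|^2 decomposes into normal^2 + shear^2
  s <- lt$segments
  expect_equal(s$magnitude^2, s$normal^2 + s$shear^2, tolerance = 1e-12)
})

test_that("segments outside the valid region are skipped with a warning", {
  n <- 11
  m <- matrix(TRUE, n, n); m[, 8:11] <- FALSE
  sxx <- matrix(1, n, n); sxx[!m] <- NA
  sig <- stressTensorField(sxx, sxx, matrix(0, n, n) + ifelse(m, 0, NA),
                           spacing = 1, mask = m)
  b <- list(cbind(x = c(1, 4), y = c(5, 5)), cbind(x = c(8.5, 10), y = c(5, 5)))
  expect_warning(lt <- lineTension(sig, b), "skipped")
  expect_equal(lt$avgNormalLineTension, 1, tolerance = 1e-12)
  expect_error(lineTension(sig, list(cbind(x = 1, y = 1))), "2 vertices")
})

test_that("scalar outputs are equivariant under a 90-degree rotation", {
  sp <- smallSpec()
  res <- squarePatchExperiment(sp, margin = 4)
  s <- res$stressRecovered
  ## rotate the frame by 90 deg: x' = y, y' = -x;
  ## sxx' = syy, syy' = sxx, sxy' = -sxy; grids transpose accordingly
  sR <- stressTensorField(t(s@syy), t(s@sxx), -t(s@sxy), spacing = s@spacing,
                          mask = t(s@mask))
  mk <- res$patchMask
  a <- stressScalars(s, mk)
  b <- stressScalars(sR, t(mk))
  expect_equal(b$avgMaxNormalStress, a$avgMaxNormalStress, tolerance = 1e-12)
  expect_equal(b$avgMaxShearStress, a$avgMaxShearStress, tolerance = 1e-12)
  expect_equal(b$cvNormalStress, a$cvNormalStress, tolerance = 1e-12)
})

test_that("contractility is continuous under vanishing balanced noise", {
  sp <- smallSpec()
  tr <- tractionFromStress(makeSquareStress(sp))
  c0 <- contractility(tr)$contractility
  set.seed(9)
  nz <- matrix(rnorm(128^2), 128); nz <- nz - mean(nz)
  for (amp in c(1e-3, 1e-5)) {
    tn <- vectorField2D(vx(tr) + amp * nz, vy(tr) + amp * t(nz), spacing = 1)
    cN <- contractility(tn)$contractility
    expect_equal(cN / c0, 1, tolerance = 10 * amp)
  }
})

test_that("results files round-trip and compare across groups", {
  sp <- smallSpec()
  res <- squarePatchExperiment(sp, margin = 4)
  rec <- resultsRecord(res$deformation, res$tractionRecovered,
                       res$stressRecovered, tractionMask = res$femMask,
                       cellMask = res$patchMask, nCells = 4)
  d <- withr::local_tempdir()
  p1 <- file.path(d, "a.txt"); p2 <- file.path(d, "b.txt")
  writeResults(rec, p1)
  rec2 <- rec; rec2$Contractility <- rec$Contractility * 1.1
  writeResults(rec2, p2)
  df <- readResults(c(p1, p2))
  expect_setequal(unique(df$quantity), names(rec))
  got <- df$value[df$quantity == "Contractility" & df$file == p1]
  expect_equal(got, rec$Contractility, tolerance = 1e-12)
  cmp <- compareResults(df)
  expect_true(all(names(rec) %in% cmp$quantity))
  expect_equal(nrow(cmp), 2 * length(rec))
})
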