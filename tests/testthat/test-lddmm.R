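# Flow integration, energy, analytic gradient, registration, cascading.

test_that("flow integration: zero velocity, constant translation, T=1", {
  g <- ImageGrid(c(16, 16))
  v0 <- lapply(1:3, function(t) VectorField(0, g))
  fl <- integrateFlow(v0)
  expect_true(all(displacement(fl$phi)[[1]] == 0))
  expect_true(all(displacement(fl$phiInv)[[1]] == 0))
  # constant field, T = 1: pure translation, phiInv displacement = -c
  c0 <- 0.06
  v <- list(VectorField(list(array(c0, c(16, 16)),
                             array(0, c(16, 16))), g))
  fl <- integrateFlow(v)
  interior <- 4:13
  expect_equal(displacement(fl$phiInv)[[1]][interior, interior],
               array(-c0, c(10, 10)), tolerance = 1e-12)
  # T = 1 small-deformation identity: phiInv = Id - v0 exactly
  set.seed(2)
  vr <- list(VectorField(list(array(rnorm(256, 0, 0.01), c(16, 16)),
                              array(rnorm(256, 0, 0.01), c(16, 16))), g))
  fl <- integrateFlow(vr)
  expect_identical(displacement(fl$phiInv)[[1]],
                   -fieldComponents(vr[[1]])[[1]])
})

test_that("flow integration converges to the exact rotation flow as T grows", {
  n <- 16
  g <- ImageGrid(c(n, n))
  omega <- 0.5
  x <- gridCoords1(n)
  vx <- outer(x, x, function(u, v) -omega * (v - 0.5))
  vy <- outer(x, x, function(u, v) omega * (u - 0.5))
  X <- outer(x, rep(1, n)); Y <- outer(rep(1, n), x)
  # phiInv is the time-1 flow of -v: rotation by -omega about the center
  rotX <- 0.5 + cos(omega) * (X - 0.5) + sin(omega) * (Y - 0.5)
  rotY <- 0.5 - sin(omega) * (X - 0.5) + cos(omega) * (Y - 0.5)
  interior <- which(sqrt((X - 0.5)^2 + (Y - 0.5)^2) < 0.25)
  errs <- sapply(c(8, 64, 512), function(T) {
    v <- lapply(seq_len(T), function(t)
      VectorField(list(vx, vy), g))
    fl <- integrateFlow(v)
    cx <- mapCoords(fl$phiInv)[[1]]
    cy <- mapCoords(fl$phiInv)[[2]]
    max(abs(cx - rotX)[interior], abs(cy - rotY)[interior])
  })
  expect_true(all(diff(errs) < 0))        # error decreases with T
  expect_lt(errs[3], 1e-3)                # O(dt) at T = 512
  expect_gt(errs[1] / errs[2], 4)         # roughly first order
})

test_that("energy: stationary case, direct-sum oracle, sigma scaling", {
  g <- ImageGrid(c(16, 16))
  I <- interiorBumps(16, 31)
  v0 <- lapply(1:4, function(t) VectorField(0, g))
  fl <- integrateFlow(v0)
  p <- LDDMMParams(alpha = 0.01, sigma = 0.7, nTimeSteps = 4)
  expect_equal(unname(computeEnergy(fl, v0, I, I, p)), c(0, 0, 0))
  I2 <- interiorBumps(16, 32)
  e <- computeEnergy(fl, v0, I, I2, p)
  directSSD <- sum((intensities(I) - intensities(I2))^2) * (1 / 16)^2
  expect_equal(unname(e["mismatch"]), directSSD / 0.7^2)
  expect_equal(unname(e["reg"]), 0)
  p2 <- LDDMMParams(alpha = 0.01, sigma = 1.4, nTimeSteps = 4)
  e2 <- computeEnergy(fl, v0, I, I2, p2)
  expect_equal(unname(e2["mismatch"]), unname(e["mismatch"]) / 4)
})

test_that("analytic gradient matches finite differences of the energy", {
  n <- 16
  g <- ImageGrid(c(n, n))
  I0 <- interiorBumps(n, 41)
  I1 <- interiorBumps(n, 42)
  p <- LDDMMParams(alpha = 0.005, sigma = 0.5, nTimeSteps = 4)
  mult <- buildMultipliers(g, p@kernel)
  T <- 4
  # stationary point: gradient vanishes when I0 = I1, v = 0
  v0 <- lapply(1:T, function(t) VectorField(0, g))
  fl0 <- integrateFlow(v0)
  gSame <- computeGradient(fl0, v0, I0, I0, p, mult)
  expect_lt(max(abs(fieldComponents(gSame[[1]])[[1]])), 1e-12)
  # at v = 0 the discrete energy's symmetric difference quotient equals
  # <grad, dv>_V to high accuracy
  gr <- computeGradient(fl0, v0, I0, I1, p, mult)
  for (s in 1:10) {
    dv <- lapply(1:T, function(t) smoothDirection(g, mult, 100 * s + t))
    eps <- 1e-5
    en <- function(sc) {
      vv <- lapply(1:T, function(t) VectorField(lapply(1:2, function(c)
        sc * fieldComponents(dv[[t]])[[c]]), g))
      ff <- integrateFlow(vv)
      computeEnergy(ff, vv, I0, I1, p, mult)["total"]
    }
    fd <- (en(eps) - en(-eps)) / (2 * eps)
    an <- flowInnerProduct(gr, dv, mult)
    expect_lt(abs(fd - an) / max(abs(fd), 1e-12), 1e-3)
  }
  # away from v = 0 the analytic gradient differs from the exact
  # derivative of the interpolated discrete energy at O(h) (within-cell
  # interpolant slopes vs. central differences), but it must remain a
  # genuine descent direction of comparable magnitude
  for (trial in 1:5) {
    vs <- lapply(1:T, function(t) {
      s <- smoothDirection(g, mult, 200 + 10 * trial + t)
      VectorField(lapply(fieldComponents(s), function(c)
        0.01 * c / max(abs(c))), g)
    })
    fls <- integrateFlow(vs)
    grs <- computeGradient(fls, vs, I0, I1, p, mult)
    dv <- lapply(grs, function(f)
      VectorField(lapply(fieldComponents(f), function(c) -c), g))
    eps <- 1e-5
    en <- function(sc) {
      vv <- lapply(1:T, function(t) VectorField(lapply(1:2, function(c)
        fieldComponents(vs[[t]])[[c]] +
          sc * fieldComponents(dv[[t]])[[c]]), g))
      ff <- integrateFlow(vv)
      computeEnergy(ff, vv, I0, I1, p, mult)["total"]
    }
    fd <- (en(eps) - en(-eps)) / (2 * eps)
    gg <- flowInnerProduct(grs, grs, mult)
    expect_lt(fd, 0)                       # descent direction
    expect_gt(fd / (-gg), 0.5)             # of comparable magnitude
    expect_lt(fd / (-gg), 2)
  }
})

test_that("registering an image to itself stays at the identity", {
  I <- blobImage(32, 0.5, 0.5)
  p <- LDDMMParams(alpha = 0.01, sigma = 1, nTimeSteps = 10,
                   maxIter = 20)
  res <- registerLDDMM(I, I, p)
  expect_lt(lddmmseg:::maxDisplacementVoxels(inverseMap(res)), 0.5)
  tr <- energyTrace(res)
  expect_lt(tr$mismatch[nrow(tr)], 1e-10)
  expectMonotoneTrace(tr)
})

test_that("registration recovers a 3-voxel translation of a blob", {
  n <- 32
  I0 <- blobImage(n, 0.45, 0.5)
  I1 <- blobImage(n, 0.45 + 3 / n, 0.5)
  p <- LDDMMParams(alpha = 0.01, gamma = 1, sigma = 1, nTimeSteps = 10,
                   maxIter = 40)
  res <- registerLDDMM(I0, I1, p)
  tr <- energyTrace(res)
  expect_lte(tr$mismatch[nrow(tr)], 0.1 * tr$mismatch[1])
  expectMonotoneTrace(tr)
  expectDiffeomorphic(inverseMap(res))
  expectDiffeomorphic(forwardMap(res))
})

test_that("fixed-step updates are available and T defaults follow the method", {
  p <- LDDMMParams()
  expect_identical(p@nTimeSteps, 10L)
  expect_identical(p@kernel@gamma, 1)
  expect_true(p@kernel@alpha >= 0.001 && p@kernel@alpha <= 0.01)
  n <- 32
  I0 <- blobImage(n, 0.45, 0.5)
  I1 <- blobImage(n, 0.45 + 2 / n, 0.5)
  pf <- LDDMMParams(alpha = 0.01, sigma = 1, nTimeSteps = 2,
                    epsilon0 = 0.05, maxIter = 5, lineSearch = FALSE)
  res <- registerLDDMM(I0, I1, pf)
  expect_identical(unique(energyTrace(res)$stepSize[-1]), 0.05)
})

test_that("cascading: degenerate single stage equals plain registration", {
  n <- 32
  I0 <- blobImage(n, 0.45, 0.5)
  I1 <- blobImage(n, 0.45 + 2 / n, 0.52)
  p <- LDDMMParams(alpha = 0.01, sigma = 1, nTimeSteps = 5, maxIter = 10)
  plain <- registerLDDMM(I0, I1, p)
  casc <- cascadeRegister(I0, I1, alphas = 0.01, params = p)
  expect_identical(displacement(inverseMap(casc)),
                   displacement(inverseMap(plain)))
  expect_equal(energyTrace(casc)$total, energyTrace(plain)$total)
  expect_error(cascadeRegister(I0, I1, alphas = c(0.002, 0.01), p),
               "decreasing")
})

test_that("cascading over decreasing alpha does not lose to single high alpha", {
  spec <- tinySpec(32, noiseSd = 0)
  base <- makePhantom(spec)
  psi <- randomDiffeomorphism(base@image@grid, 3, seed = 8)
  target <- warpImage(subjectImage(base), psi)
  p <- LDDMMParams(sigma = 0.3, nTimeSteps = 10, maxIter = 15)
  single <- registerLDDMM(subjectImage(base), target, p)
  casc <- cascadeRegister(subjectImage(base), target,
                          alphas = c(0.01, 0.005, 0.002), params = p)
  mm <- function(r) { tr <- energyTrace(r); tr$mismatch[nrow(tr)] }
  expect_lte(mm(casc), mm(single))
  expectDiffeomorphic(inverseMap(casc))
  expect_false(casc@metricRetained)
  expectMonotoneTrace(energyTrace(casc))
})
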