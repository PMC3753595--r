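# Grid geometry, interpolation, map composition, differential operators.

test_that("grids place voxel centers inside the unit cube", {
  g <- ImageGrid(c(8, 16))
  expect_equal(g@spacing, c(1 / 8, 1 / 16))
  for (a in 1:2) {
    x <- g@origin[a] + (seq_len(g@shape[a]) - 0.5) * g@spacing[a]
    expect_true(all(x > 0 & x < 1))
  }
  expect_error(ImageGrid(c(3, 8)), "extents")
})

test_that("identity map has zero displacement and unit Jacobian", {
  g <- ImageGrid(c(4, 4))
  id <- identityMap(g)
  expect_true(all(displacement(id)[[1]] == 0))
  expect_true(all(displacement(id)[[2]] == 0))
  expect_equal(mapCoords(id)[[1]][, 1], (1:4 - 0.5) / 4)
  expect_true(all(intensities(jacobianDeterminant(id)) == 1))
})

test_that("linear interpolation is exact at voxel centers and on affine images", {
  n <- 12
  g <- ImageGrid(c(n, n))
  x <- gridCoords1(n)
  I <- ScalarImage(outer(x, x, function(u, v) 2 * u - 3 * v + 0.5), g)
  # voxel centers reproduce stored values
  ctrs <- cbind(rep(x, times = n), rep(x, each = n))
  expect_equal(sampleLinear(I, ctrs), as.vector(intensities(I)))
  # midpoint of two centers on a ramp = arithmetic mean
  mid <- cbind((x[3] + x[4]) / 2, x[5])
  expect_equal(sampleLinear(I, mid),
               (intensities(I)[3, 5] + intensities(I)[4, 5]) / 2)
  # random interior points reproduce the affine function exactly
  set.seed(7)
  pts <- cbind(runif(100, x[1], x[n]), runif(100, x[1], x[n]))
  expect_equal(sampleLinear(I, pts),
               2 * pts[, 1] - 3 * pts[, 2] + 0.5, tolerance = 1e-12)
  expect_error(sampleLinear(I, cbind(NA, 0.5)), "finite")
})

test_that("nearest sampling returns the closest center and never invents labels", {
  n <- 8
  g <- ImageGrid(c(n, n))
  set.seed(3)
  lab <- array(sample(c(0L, 2L, 5L), n * n, replace = TRUE), c(n, n))
  L <- LabelImage(lab, g, labelNames = c(`2` = "a", `5` = "b"))
  x <- gridCoords1(n)
  ctrs <- cbind(rep(x, times = n), rep(x, each = n))
  expect_identical(sampleNearest(L, ctrs), as.vector(lab))
  expect_identical(labelArray(warpLabels(L, identityMap(g))), lab)
  # brute-force nearest-center scan at random points
  set.seed(4)
  pts <- cbind(runif(60), runif(60))
  got <- sampleNearest(L, pts)
  for (k in seq_len(nrow(pts))) {
    dists <- outer(x, x, function(u, v)
      (u - pts[k, 1])^2 + (v - pts[k, 2])^2)
    expect_identical(got[k], lab[which.min(dists)])
  }
  expect_true(all(got %in% c(0L, 2L, 5L)))
})

test_that("map composition obeys identity laws and a pointwise oracle", {
  g <- ImageGrid(c(8, 8))
  set.seed(11)
  mk <- function(sd) DeformationMap(list(
    array(rnorm(64, 0, sd), c(8, 8)), array(rnorm(64, 0, sd), c(8, 8))), g)
  f <- mk(0.01)
  id <- identityMap(g)
  # identity laws exact on the stored displacement
  expect_identical(displacement(composeMaps(id, f)), displacement(f))
  expect_identical(displacement(composeMaps(f, id)), displacement(f))
  # translation pair cancels in the interior
  tr <- function(s) DeformationMap(list(array(s, c(8, 8)),
                                        array(0, c(8, 8))), g)
  cc <- composeMaps(tr(2 / 8), tr(-2 / 8))
  interior <- 3:6
  expect_lt(max(abs(displacement(cc)[[1]][interior, interior])), 1e-12)
  # pointwise oracle: naive per-voxel evaluation
  h <- mk(0.01)
  comp <- composeMaps(f, h)
  x <- gridCoords1(8)
  for (j in 1:8) for (i in 1:8) {
    inner <- c(x[i] + displacement(h)[[1]][i, j],
               x[j] + displacement(h)[[2]][i, j])
    expected <- c(
      inner[1] + naiveBilinear(displacement(f)[[1]], inner),
      inner[2] + naiveBilinear(displacement(f)[[2]], inner))
    got <- c(mapCoords(comp)[[1]][i, j], mapCoords(comp)[[2]][i, j])
    expect_equal(got, expected, tolerance = 1e-12)
  }
  # grid mismatch is an error
  expect_error(composeMaps(f, identityMap(ImageGrid(c(16, 16)))), "grid")
})

test_that("Jacobian determinant matches closed forms and analytic oracle", {
  n <- 16
  g <- ImageGrid(c(n, n))
  x <- gridCoords1(n)
  # uniform scaling about 0: coords s*x -> det s^d in the interior
  s <- 1.1
  sc <- DeformationMap(list(
    outer(x, rep(1, n)) * (s - 1), outer(rep(1, n), x) * (s - 1)), g)
  det_sc <- intensities(jacobianDeterminant(sc))
  expect_equal(det_sc[3:(n - 2), 3:(n - 2)],
               array(s^2, c(n - 4, n - 4)), tolerance = 1e-10)
  # quadratic map: central differences are exact in the interior
  u1 <- outer(x, x, function(u, v) 0.02 * u^2 + 0.01 * v)
  u2 <- outer(x, x, function(u, v) -0.015 * v^2 + 0.005 * u * v)
  m <- DeformationMap(list(u1, u2), g)
  X <- outer(x, rep(1, n)); Y <- outer(rep(1, n), x)
  a11 <- 1 + 0.04 * X; a12 <- array(0.01, c(n, n))
  a21 <- 0.005 * Y;    a22 <- 1 - 0.03 * Y + 0.005 * X
  expected <- a11 * a22 - a12 * a21
  got <- intensities(jacobianDeterminant(m))
  interior <- 2:(n - 1)
  expect_equal(got[interior, interior], expected[interior, interior],
               tolerance = 1e-10)
})

test_that("spatial gradient matches analytic derivatives at O(h^2)", {
  g <- ImageGrid(c(16, 16))
  expect_equal(fieldComponents(spatialGradient(
    ScalarImage(array(3, c(16, 16)), g)))[[1]],
    array(0, c(16, 16)))
  x <- gridCoords1(16)
  ramp <- ScalarImage(outer(x, x, function(u, v) 4 * u - 2 * v), g)
  gr <- spatialGradient(ramp)
  interior <- 2:15
  expect_equal(fieldComponents(gr)[[1]][interior, interior],
               array(4, c(14, 14)), tolerance = 1e-10)
  expect_equal(fieldComponents(gr)[[2]][interior, interior],
               array(-2, c(14, 14)), tolerance = 1e-10)
  # cubic image: error shrinks ~4x when h halves
  err <- sapply(c(16, 32), function(n) {
    gn <- ImageGrid(c(n, n))
    xn <- gridCoords1(n)
    I <- ScalarImage(outer(xn, xn, function(u, v) u^3 + v^3), gn)
    gx <- fieldComponents(spatialGradient(I))[[1]]
    truth <- outer(xn, xn, function(u, v) 3 * u^2)
    inn <- 2:(n - 1)
    max(abs(gx - truth)[inn, inn])
  })
  expect_gt(err[1] / err[2], 3)
})

test_that("3-D warping, Jacobian and composition are consistent", {
  g <- ImageGrid(c(8, 8, 8))
  set.seed(21)
  m <- randomDiffeomorphism(g, 0.8, seed = 5)
  expectDiffeomorphic(m)
  inv <- invertMap(m)
  round <- composeMaps(m, inv)
  expect_lt(maxDisp <- max(abs(displacement(round)[[1]])) * 8, 0.1)
  s <- 1.05
  x <- gridCoords1(8)
  sc <- DeformationMap(lapply(1:3, function(c) {
    arr <- array(0, c(8, 8, 8))
    sweep(arr, c, x * (s - 1), "+")
  }), g)
  det_sc <- intensities(jacobianDeterminant(sc))
  expect_equal(det_sc[3:6, 3:6, 3:6], array(s^3, c(4, 4, 4)),
               tolerance = 1e-10)
})
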