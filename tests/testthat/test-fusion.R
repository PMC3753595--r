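# Label propagation, majority vote, EM likelihood fusion, pipelines.

test_that("label propagation shifts labels with the map", {
  n <- 16
  g <- ImageGrid(c(n, n))
  lab <- array(0L, c(n, n))
  lab[5:8, 5:8] <- 1L
  L <- LabelImage(lab, g, labelNames = c(`1` = "box"))
  expect_identical(labelArray(propagateLabels(L, identityMap(g))), lab)
  # pullback through a +2-voxel shift map moves content 2 voxels down
  shift <- DeformationMap(list(array(2 / n, c(n, n)),
                               array(0, c(n, n))), g)
  moved <- propagateLabels(L, shift)
  expected <- array(0L, c(n, n))
  expected[3:6, 5:8] <- 1L
  expect_identical(labelArray(moved), expected)
  # a solver-produced diffeomorphism keeps every ROI populated
  m <- randomDiffeomorphism(g, 1.5, seed = 12)
  warped <- propagateLabels(L, m)
  expect_gt(sum(labelArray(warped) == 1L), 0)
  expect_true(all(labelArray(warped) %in% c(0L, 1L)))
})

test_that("majority vote fuses by per-voxel mode with smallest-id ties", {
  n <- 8
  g <- ImageGrid(c(n, n))
  mk <- function(arr) LabelImage(arr, g, labelNames = c(`1` = "a",
                                                        `2` = "b"))
  base <- array(1L, c(n, n))
  expect_identical(labelArray(majorityVote(list(mk(base)))), base)
  expect_identical(labelArray(majorityVote(list(mk(base), mk(base),
                                                mk(base)))), base)
  dissent <- base
  dissent[3, 3] <- 2L
  fused <- majorityVote(list(mk(base), mk(base), mk(dissent)))
  expect_identical(labelArray(fused), base)
  # 1-1 tie between ids 2 and 1 goes to 1
  tie <- majorityVote(list(mk(base), mk(dissent)))
  expect_identical(labelArray(tie)[3, 3], 1L)
  expect_error(majorityVote(list()), "empty")
})

test_that("EM fusion: symmetry, degenerate single atlas, sharp posterior", {
  n <- 16
  g <- ImageGrid(c(n, n))
  I <- interiorBumps(n, 71)
  lab <- array(0L, c(n, n)); lab[6:10, 6:10] <- 1L
  L <- LabelImage(lab, g, labelNames = c(`1` = "roi"))
  same <- list(image = I, labels = L)
  # identical atlases: uniform weights, labels preserved, N-invariance
  for (J in c(2, 4)) {
    fr <- likelihoodFusionEM(I, rep(list(same), J),
                             FusionParams(noiseVar = 0.01))
    expect_equal(mixingProportions(fr), rep(1 / J, J), tolerance = 1e-9)
    for (w in fusionWeights(fr))
      expect_equal(w, array(1 / J, c(n, n)), tolerance = 1e-9)
    expect_identical(labelArray(fusedLabels(fr)), lab)
  }
  # single atlas: fusion reduces to the propagated labels
  fr1 <- likelihoodFusionEM(I, list(same), FusionParams(noiseVar = 0.01))
  expect_identical(labelArray(fusedLabels(fr1)), lab)
  # two atlases, one matching exactly, one far off: sharp weights
  off <- list(image = ScalarImage(intensities(I) + 0.5, g),
              labels = LabelImage(array(2L, c(n, n)), g,
                                  labelNames = c(`2` = "other")))
  fr2 <- likelihoodFusionEM(I, list(same, off),
                            FusionParams(maxEmIter = 20L))
  expect_true(all(fusionWeights(fr2)[[1]] > 0.99))
  expect_identical(labelArray(fusedLabels(fr2)), lab)
})

test_that("EM invariants: convex weights and non-decreasing log-likelihood", {
  n <- 16
  g <- ImageGrid(c(n, n))
  set.seed(81)
  I <- interiorBumps(n, 81)
  mkAtlas <- function(seed) {
    set.seed(seed)
    img <- ScalarImage(intensities(I) +
                       array(rnorm(n * n, 0, 0.05), c(n, n)), g)
    lab <- array(0L, c(n, n))
    lab[sample(n * n, 40)] <- sample(1:2, 40, replace = TRUE)
    list(image = img, labels = LabelImage(lab,
         g, labelNames = c(`1` = "a", `2` = "b")))
  }
  deformed <- lapply(1:4, mkAtlas)
  fr <- likelihoodFusionEM(I, deformed,
                           FusionParams(maxEmIter = 15L, emTol = 0))
  expect_true(all(diff(emTrace(fr)) >= -1e-8 * abs(emTrace(fr)[-1])))
  Wsum <- Reduce(`+`, fusionWeights(fr))
  expect_equal(Wsum, array(1, c(n, n)), tolerance = 1e-9)
  expect_true(all(vapply(fusionWeights(fr),
                         function(w) all(w >= 0), logical(1))))
  expect_equal(sum(mixingProportions(fr)), 1, tolerance = 1e-9)
})

test_that("neighborhood-averaged residuals are accepted and stay convex", {
  n <- 12
  g <- ImageGrid(c(n, n))
  I <- interiorBumps(n, 91)
  a1 <- list(image = I, labels = LabelImage(array(1L, c(n, n)), g,
                                            labelNames = c(`1` = "a")))
  a2 <- list(image = ScalarImage(intensities(I) + 0.2, g),
             labels = LabelImage(array(2L, c(n, n)), g,
                                 labelNames = c(`2` = "b")))
  fr <- likelihoodFusionEM(I, list(a1, a2),
                           FusionParams(neighborhoodRadius = 1L))
  Wsum <- Reduce(`+`, fusionWeights(fr))
  expect_equal(Wsum, array(1, c(n, n)), tolerance = 1e-9)
  expect_identical(labelArray(fusedLabels(fr)),
                   array(1L, c(n, n)))
})

test_that("single-atlas pipeline reproduces its own atlas", {
  spec <- tinySpec(32, noiseSd = 0.01)
  base <- makePhantom(spec)
  atlas <- AtlasEntry(subjectImage(base), subjectLabels(base), id = "self")
  p <- LDDMMParams(sigma = 0.5, nTimeSteps = 5, maxIter = 10)
  seg <- segmentSingleAtlas(atlas, subjectImage(base), p, alphas = 0.01)
  m <- evaluateROIs(seg, subjectLabels(base))
  expect_true(all(m$kappa > 0.99))
  # no label invention
  expect_true(all(unique(as.vector(labelArray(seg))) %in%
                  c(0L, 1L, 2L)))
})
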