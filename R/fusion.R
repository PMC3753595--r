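# Single-atlas label propagation and multi-atlas EM likelihood fusion.

#' Construct an atlas entry
#'
#' @param image intensity [ScalarImage-class].
#' @param labels [LabelImage-class] of ROI charts on the same grid.
#' @param id atlas name.
#' @return an [AtlasEntry-class]
#' @export
AtlasEntry <- function(image, labels, id = "atlas") {
  new("AtlasEntry", image = image, labels = labels, id = as.character(id))
}

#' Construct fusion parameters
#'
#' @param noiseVar initial Gaussian likelihood variance; NA (default)
#'   initializes from the mean squared atlas-target residual.
#' @param maxEmIter EM iteration cap (default 10).
#' @param emTol relative log-likelihood change tolerance (default 1e-6).
#' @param neighborhoodRadius 0 (default) for pointwise residuals, r > 0
#'   to average squared residuals over a (2r+1)^d voxel box.
#' @param tieBreak label tie-break rule; "smallest" (the only rule) picks
#'   the smallest label id.
#' @return a [FusionParams-class]
#' @export
FusionParams <- function(noiseVar = NA_real_, maxEmIter = 10L,
                         emTol = 1e-6, neighborhoodRadius = 0L,
                         tieBreak = "smallest") {
  new("FusionParams", noiseVar = as.numeric(noiseVar),
      maxEmIter = as.integer(maxEmIter), emTol = as.numeric(emTol),
      neighborhoodRadius = as.integer(neighborhoodRadius),
      tieBreak = tieBreak)
}

#' Propagate atlas labels through a registration map
#'
#' Nearest-neighbor pullback of the atlas charts through the backward map
#' `phi^-1`, the same convention used to deform the atlas image; the
#' label alphabet is preserved.
#'
#' @param atlasLabels a [LabelImage-class].
#' @param phiInv a [DeformationMap-class] on the same grid (e.g.
#'   `inverseMap(result)`).
#' @return a [LabelImage-class] in subject space
#' @export
propagateLabels <- function(atlasLabels, phiInv) {
  warpLabels(atlasLabels, phiInv)
}

#' Majority-vote fusion of candidate segmentations
#'
#' Per-voxel modal label across the stack; ties go to the smallest label
#' id. A baseline to compare the likelihood fusion against.
#'
#' @param labelStack non-empty list of [LabelImage-class] objects on a
#'   common grid.
#' @return a [LabelImage-class]
#' @export
majorityVote <- function(labelStack) {
  if (length(labelStack) == 0L) stop("empty label stack", call. = FALSE)
  grid <- labelStack[[1]]@grid
  for (l in labelStack) stopIfGridMismatch(grid, l@grid, "stacked labels")
  mats <- vapply(labelStack, function(l) as.vector(l@labels),
                 integer(nVoxels(grid)))
  mats <- matrix(mats, nrow = nVoxels(grid))
  ids <- sort(unique(as.vector(mats)))
  counts <- vapply(ids, function(id) rowSums(mats == id),
                   numeric(nrow(mats)))
  counts <- matrix(counts, nrow = nrow(mats))
  win <- ids[max.col(counts, ties.method = "first")] # ids sorted: smallest wins
  names <- do.call(c, unname(lapply(labelStack, function(l) l@labelNames)))
  names <- names[!duplicated(names(names))]
  LabelImage(array(as.integer(win), dim_of(grid)), grid,
             labelNames = names)
}

# Box average of an array over a (2r+1)^d neighborhood, partial windows
# renormalized at the edges.
boxMean <- function(arr, r) {
  if (r == 0L) return(arr)
  ones <- array(1, dim(arr))
  num <- arr
  den <- ones
  for (a in seq_along(dim(arr))) {
    n <- dim(arr)[a]
    acc <- function(x) {
      out <- array(0, dim(x))
      for (s in -r:r) {
        idx <- pmin(pmax(seq_len(n) + s, 1L), n)
        sel <- seq_len(n) + s >= 1L & seq_len(n) + s <= n
        shifted <- indexAxis(x, a, idx)
        # zero out contributions that fell off the edge
        mask <- as.numeric(sel)
        out <- out + sweep(shifted, a, mask, "*")
      }
      out
    }
    num <- acc(num)
    den <- acc(den)
  }
  num / den
}

#' Multi-atlas likelihood fusion by expectation-maximization
#'
#' The target intensities are modeled as a Gaussian mixture over the
#' deformed atlases: voxel x drawn from atlas j has mean `M_j(x)` (the
#' deformed atlas intensity) and shared variance `sigma_f^2`, with global
#' mixing priors `pi_j`. The E-step computes per-voxel responsibilities
#' `w_j(x)` proportional to
#' `pi_j exp(-(I(x) - M_j(x))^2 / (2 sigma_f^2))`; the
#' M-step re-estimates `pi_j` as the mean responsibility and `sigma_f^2`
#' as the responsibility-weighted mean squared residual. The fused label
#' at x is `argmax_l sum_j w_j(x) 1[L_j(x) = l]` (ties to the smallest
#' id). The observed-data log-likelihood is non-decreasing across
#' iterations (for the pointwise model).
#'
#' @param target subject [ScalarImage-class].
#' @param deformed list of `list(image =, labels =)` pairs: atlas images
#'   and charts already mapped into subject space.
#' @param params a [FusionParams-class].
#' @return a [FusionResult-class]
#' @export
likelihoodFusionEM <- function(target, deformed,
                               params = FusionParams()) {
  J <- length(deformed)
  if (J == 0L) stop("need at least one deformed atlas", call. = FALSE)
  grid <- target@grid
  for (a in deformed) {
    stopIfGridMismatch(grid, a$image@grid, "target and deformed atlas")
    stopIfGridMismatch(grid, a$labels@grid, "target and deformed labels")
  }
  n <- nVoxels(grid)
  I <- as.vector(target@values)
  r <- params@neighborhoodRadius
  sq <- vapply(deformed, function(a) {
    res2 <- (target@values - a$image@values)^2
    as.vector(boxMean(res2, r))
  }, numeric(n))
  sq <- matrix(sq, nrow = n)
  pii <- rep(1 / J, J)
  s2 <- if (is.na(params@noiseVar)) mean(sq) else params@noiseVar
  if (s2 < 1e-12)
    stop("initial noise variance below 1e-12 (atlases fit the target ",
         "exactly); set a noise floor via FusionParams(noiseVar = )",
         call. = FALSE)
  trace <- numeric(0)
  W <- NULL
  for (it in seq_len(params@maxEmIter)) {
    # E-step (log-space for stability)
    logp <- sweep(-sq / (2 * s2), 2, log(pii), "+") -
      0.5 * log(2 * pi * s2)
    mx <- apply(logp, 1, max)
    pz <- exp(logp - mx)
    rs <- rowSums(pz)
    W <- pz / rs
    ll <- sum(mx + log(rs))
    trace <- c(trace, ll)
    if (it > 1L &&
        abs(trace[it] - trace[it - 1L]) <=
          params@emTol * max(abs(trace[it - 1L]), 1)) break
    # M-step; the variance update is floored at 1e-12 (a constrained
    # M-step, so the likelihood ascent is preserved) to keep the E-step
    # well defined when one atlas fits essentially exactly
    pii <- colMeans(W)
    pii <- pmax(pii, 1e-12); pii <- pii / sum(pii)
    s2 <- max(sum(W * sq) / sum(W), 1e-12)
  }
  # MAP label: responsibility-weighted vote, ties to the smallest id
  Lmat <- vapply(deformed, function(a) as.vector(a$labels@labels),
                 integer(n))
  Lmat <- matrix(Lmat, nrow = n)
  ids <- sort(unique(as.vector(Lmat)))
  score <- vapply(ids, function(id) rowSums(W * (Lmat == id)),
                  numeric(n))
  score <- matrix(score, nrow = n)
  win <- ids[max.col(score, ties.method = "first")]
  names <- do.call(c, unname(lapply(deformed, function(a) a$labels@labelNames)))
  names <- names[!duplicated(names(names))]
  fused <- LabelImage(array(as.integer(win), dim_of(grid)), grid,
                      labelNames = names)
  weights <- lapply(seq_len(J),
                    function(j) array(W[, j], dim_of(grid)))
  new("FusionResult", labels = fused, weights = weights, mixing = pii,
      emTrace = trace)
}

#' Single-atlas segmentation pipeline
#'
#' Histogram-matches the atlas to the subject, optionally pre-aligns it
#' with the moment-based affine, registers it (cascaded over `alphas`
#' when more than one is given), and propagates the atlas charts to
#' subject space through the composed map. Deterministic given the
#' parameters.
#'
#' @param atlas an [AtlasEntry-class].
#' @param subject subject [ScalarImage-class].
#' @param params an [LDDMMParams-class].
#' @param alphas cascade schedule (default `c(0.01, 0.005, 0.002)`);
#'   a single value runs a plain registration.
#' @param histMatch apply histogram matching first (default TRUE).
#' @param prealign apply the moment affine first (default FALSE; phantom
#'   populations are generated pose-aligned).
#' @param details if TRUE return a list with the labels, registration
#'   result, affine and deformed atlas image instead of just the labels.
#' @return a [LabelImage-class] in subject space (or a list, see
#'   `details`)
#' @export
segmentSingleAtlas <- function(atlas, subject, params = LDDMMParams(),
                               alphas = c(0.01, 0.005, 0.002),
                               histMatch = TRUE, prealign = FALSE,
                               details = FALSE) {
  matched <- atlas@image
  if (histMatch) matched <- histogramMatch(matched, subject)
  img <- matched
  affine <- NULL
  if (prealign) {
    affine <- momentPrealign(img, subject)
    img <- applyAffine(img, affine, subject@grid)
  }
  res <- if (length(alphas) > 1L)
    cascadeRegister(img, subject, alphas, params)
  else {
    p <- params
    p@kernel <- KernelParams(alphas, params@kernel@gamma)
    registerLDDMM(img, subject, p)
  }
  pullMap <- if (is.null(affine)) res@phiInv
    else composeAffineInvWithMap(affine, res@phiInv)
  labels <- propagateLabels(atlas@labels, pullMap)
  if (!details) return(labels)
  list(labels = labels, registration = res, affine = affine,
       deformedImage = warpImage(matched, pullMap),
       pullMap = pullMap)
}

#' Multi-atlas segmentation with likelihood fusion
#'
#' Registers each atlas to the subject independently (complexity linear
#' in the number of atlases), deforms images (multilinear) and charts
#' (nearest-neighbor) into subject space, and fuses them with
#' [likelihoodFusionEM()].
#'
#' @param atlases list of at least two [AtlasEntry-class] objects.
#' @param subject subject [ScalarImage-class].
#' @param params an [LDDMMParams-class] shared by all registrations.
#' @param fusion a [FusionParams-class].
#' @inheritParams segmentSingleAtlas
#' @param deformed optionally, precomputed per-atlas
#'   `list(image =, labels =)` pairs in subject space (skips the
#'   registrations; used to reuse single-atlas runs).
#' @return a [FusionResult-class]
#' @export
segmentMultiAtlas <- function(atlases, subject, params = LDDMMParams(),
                              fusion = FusionParams(),
                              alphas = c(0.01, 0.005, 0.002),
                              histMatch = TRUE, prealign = FALSE,
                              deformed = NULL) {
  if (is.null(deformed)) {
    if (length(atlases) < 2L)
      stop("need at least two atlases", call. = FALSE)
    deformed <- lapply(atlases, function(a) {
      s <- segmentSingleAtlas(a, subject, params, alphas, histMatch,
                              prealign, details = TRUE)
      list(image = s$deformedImage, labels = s$labels)
    })
  }
  likelihoodFusionEM(subject, deformed, fusion)
}
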