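# Synthetic labeled brain-like phantoms with known ground-truth
# deformations, so every pipeline stage is testable without external
# data.

#' Construct a phantom specification
#'
#' @param shape grid extents (2 or 3 axes).
#' @param structures data.frame with columns `name`, `intensity`,
#'   per-axis centers `c1..cd` and radii `r1..rd` in domain units; every
#'   radius must exceed one voxel.
#' @param backgroundIntensity background level (default 0.25).
#' @param noiseSd additive Gaussian noise sd (default 0.02, i.e. 2% of
#'   the unit dynamic range).
#' @param seed integer driving the noise.
#' @return a [PhantomSpec-class]
#' @export
PhantomSpec <- function(shape, structures, backgroundIntensity = 0.25,
                        noiseSd = 0.02, seed = 1L) {
  new("PhantomSpec", shape = as.integer(shape),
      structures = as.data.frame(structures),
      backgroundIntensity = as.numeric(backgroundIntensity),
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

# The 14-structure subcortical-style layout: left/right pairs of
# ventricle, caudate, putamen, globus pallidus, thalamus, hippocampus and
# amygdala, mirrored about the mid-sagittal plane, with adjacent
# intensities separated by at least 20% of the dynamic range.
subcorticalLayout2D <- function() {
  base <- data.frame(
    name      = c("ventricle", "caudate", "putamen", "globus_pallidus",
                  "thalamus", "hippocampus", "amygdala"),
    dx        = c(0.10, 0.24, 0.38, 0.26, 0.12, 0.30, 0.14),
    cy        = c(0.70, 0.74, 0.62, 0.56, 0.44, 0.32, 0.22),
    rx        = c(0.050, 0.045, 0.050, 0.045, 0.065, 0.060, 0.050),
    ry        = c(0.110, 0.075, 0.085, 0.050, 0.080, 0.050, 0.045),
    intensity = c(0.10, 0.85, 0.70, 0.55, 0.40, 0.62, 0.78))
  left <- data.frame(name = paste0("left_", base$name),
                     intensity = base$intensity,
                     c1 = 0.5 - base$dx, c2 = base$cy,
                     r1 = base$rx, r2 = base$ry)
  right <- data.frame(name = paste0("right_", base$name),
                      intensity = base$intensity,
                      c1 = 0.5 + base$dx, c2 = base$cy,
                      r1 = base$rx, r2 = base$ry)
  rbind(left, right)
}

#' Default subcortical-style phantom specification
#'
#' Fourteen smooth ellipsoidal structures (left/right pairs of ventricle,
#' caudate, putamen, globus pallidus, thalamus, hippocampus, amygdala)
#' on a T1-like background. 2-D shapes use the mid-axial layout; 3-D
#' shapes extrude it with a finite z extent. Presets: `c(64, 64)` for
#' fast 2-D work, `c(32, 32, 32)` or `c(64, 64, 64)` in 3-D.
#'
#' @param shape grid extents (default `c(64, 64)`).
#' @param noiseSd additive Gaussian noise sd (default 0.02).
#' @param seed integer seed.
#' @return a [PhantomSpec-class]
#' @export
defaultPhantomSpec <- function(shape = c(64, 64), noiseSd = 0.02,
                               seed = 1L) {
  st <- subcorticalLayout2D()
  if (length(shape) == 3L) {
    st$c3 <- 0.5
    st$r3 <- pmax(st$r1, st$r2)
  }
  d <- length(shape)
  st <- st[, c("name", "intensity", paste0("c", seq_len(d)),
               paste0("r", seq_len(d)))]
  PhantomSpec(shape, st, noiseSd = noiseSd, seed = seed)
}

# Normalized ellipsoid radius field r(x) = sqrt(sum ((x-c)/rad)^2) for
# one structure, on the full grid.
structureRadius <- function(grid, center, radii) {
  d <- gridDim(grid)
  r2 <- array(0, dim_of(grid))
  for (a in seq_len(d)) {
    r2 <- r2 + sweep(array(0, dim_of(grid)), a,
                     ((axisCenters(grid, a) - center[a]) / radii[a])^2,
                     "+")
  }
  sqrt(r2)
}

#' Generate a labeled phantom
#'
#' Smooth-edged ellipsoidal structures on a uniform background: each
#' structure's intensity ramps linearly from the background to its
#' plateau over roughly one voxel at the ellipsoid surface. Labels are
#' the noise-free ellipsoid memberships (so they are invariant to
#' `noiseSd`); additive Gaussian noise is applied to the intensities
#' only. Generation is bit-reproducible from the spec's seed, and
#' overlapping structures are rejected with an error naming the pair.
#'
#' @param spec a [PhantomSpec-class].
#' @return a [GroundTruth-class] with `deformation = NULL`
#' @export
makePhantom <- function(spec) {
  grid <- ImageGrid(spec@shape)
  d <- gridDim(grid)
  st <- spec@structures
  img <- array(spec@backgroundIntensity, dim_of(grid))
  lab <- array(0L, dim_of(grid))
  for (k in seq_len(nrow(st))) {
    center <- as.numeric(st[k, paste0("c", seq_len(d))])
    radii <- as.numeric(st[k, paste0("r", seq_len(d))])
    r <- structureRadius(grid, center, radii)
    inside <- r < 1
    if (any(lab[inside] != 0L)) {
      other <- unique(lab[inside][lab[inside] != 0L])[1]
      stop("structures overlap: '", st$name[k], "' and '",
           st$name[other], "'", call. = FALSE)
    }
    lab[inside] <- k
    # ~1 voxel intensity ramp at the surface
    edge <- 1 / (mean(radii) * mean(spec@shape))
    w <- pmin(pmax((1 - r) / edge, 0), 1)
    img <- img + w * (st$intensity[k] - spec@backgroundIntensity)
  }
  if (spec@noiseSd > 0) {
    withr_seed <- spec@seed
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(withr_seed)
    img <- img + array(stats::rnorm(length(img), 0, spec@noiseSd),
                       dim(img))
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  names <- stats::setNames(st$name, as.character(seq_len(nrow(st))))
  new("GroundTruth",
      image = ScalarImage(img, grid),
      labels = LabelImage(lab, grid, labelNames = names),
      deformation = NULL)
}

#' Generate a random diffeomorphism in the kernel's deformation class
#'
#' White-noise vector fields smoothed by the registration kernel K,
#' rescaled so each of `steps` composition steps moves at most
#' `amplitudeVoxels / steps` voxels, then composed. The Jacobian
#' determinant is verified strictly positive at every voxel; on failure
#' the amplitude is halved and the construction retried (at most 5
#' times).
#'
#' @param grid an [ImageGrid-class].
#' @param amplitudeVoxels total displacement budget in voxels.
#' @param smoothness a [KernelParams-class] for the smoothing kernel
#'   (default alpha 0.01, gamma 1).
#' @param steps composition steps; by default enough that each step
#'   moves well under 0.4 voxel.
#' @param seed integer seed.
#' @return a verified-diffeomorphic [DeformationMap-class]
#' @export
randomDiffeomorphism <- function(grid, amplitudeVoxels,
                                 smoothness = KernelParams(0.01, 1),
                                 steps = max(1L,
                                   ceiling(amplitudeVoxels / 0.35)),
                                 seed = 1L) {
  if (amplitudeVoxels / steps >= 0.4)
    stop("per-step displacement must stay under 0.4 voxel; ",
         "increase steps", call. = FALSE)
  if (amplitudeVoxels == 0) return(identityMap(grid))
  mult <- buildMultipliers(grid, smoothness)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  amp <- amplitudeVoxels
  for (attempt in seq_len(5L)) {
    noise <- VectorField(lapply(seq_along(grid@shape), function(c) {
      array(stats::rnorm(nVoxels(grid)), dim_of(grid))
    }), grid)
    sm <- applyK(noise, mult)
    stepVox <- amp / steps
    mx <- max(vapply(seq_along(sm@components), function(c) {
      max(abs(sm@components[[c]])) / grid@spacing[c]
    }, numeric(1)))
    scale <- stepVox / mx
    step <- DeformationMap(lapply(sm@components, function(c) scale * c),
                           grid)
    map <- identityMap(grid)
    for (s in seq_len(steps)) map <- composeMaps(map, step)
    if (min(jacobianDeterminant(map)@values) > 0) return(map)
    amp <- amp / 2
  }
  stop("could not construct a positive-Jacobian map in 5 retries",
       call. = FALSE)
}

#' Generate a population of deformed phantom subjects
#'
#' Subject i is the base phantom pulled back through an independent
#' [randomDiffeomorphism()] (intensities multilinearly, ground-truth
#' labels nearest-neighbor through the same map) with independent
#' additive noise. Deterministic given `(base, seed)`; all subjects
#' share the base label alphabet, and each carries its known deformation.
#'
#' @param base a [PhantomSpec-class].
#' @param nSubjects number of subjects (>= 1).
#' @param deformAmplitude deformation amplitude in voxels (default 2).
#' @param seed integer seed.
#' @param smoothness kernel for the deformation generator.
#' @return list of [GroundTruth-class] subjects
#' @export
makePopulation <- function(base, nSubjects, deformAmplitude = 2,
                           seed = 1L,
                           smoothness = KernelParams(0.01, 1)) {
  stopifnot(nSubjects >= 1L)
  clean <- base
  clean@noiseSd <- 0
  truthBase <- makePhantom(clean)
  grid <- truthBase@image@grid
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  lapply(seq_len(nSubjects), function(i) {
    psi <- randomDiffeomorphism(grid, deformAmplitude,
                                smoothness = smoothness,
                                seed = seed * 1000L + i)
    img <- warpImage(truthBase@image, psi)
    lab <- warpLabels(truthBase@labels, psi)
    if (base@noiseSd > 0) {
      set.seed(seed * 2000L + i)
      img <- ScalarImage(img@values +
        array(stats::rnorm(nVoxels(grid), 0, base@noiseSd),
              dim_of(grid)), grid)
    }
    new("GroundTruth", image = img, labels = lab, deformation = psi)
  })
}
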