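#' @import methods
NULL

#' Regular image grid on the unit cube
#'
#' Geometry shared by every image, field and map in the package. A grid of
#' `shape[d]` voxels per axis discretizes the domain Omega = [0,1]^d with
#' cell-centered coordinates: voxel `i` (1-based) along axis `d` sits at
#' `origin[d] + (i - 0.5) * spacing[d]` with `spacing[d] = 1/shape[d]`, so
#' the physical domain is the unit square/cube regardless of resolution.
#'
#' @slot shape integer extents per axis (2 or 3 axes, each >= 4).
#' @slot spacing physical step per axis, `1/shape`.
#' @slot origin corner coordinate (default 0 per axis).
#' @export
setClass("ImageGrid",
  representation(shape = "integer", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    d <- length(object@shape)
    if (!(d %in% c(2L, 3L))) return("grid must have 2 or 3 axes")
    if (length(object@spacing) != d || length(object@origin) != d)
      return("shape, spacing and origin must have equal length")
    if (any(object@shape < 4L)) return("all extents must be >= 4")
    if (any(object@spacing <= 0)) return("all spacings must be > 0")
    TRUE
  })

#' Scalar intensity volume
#'
#' @slot grid the [ImageGrid-class] the values live on.
#' @slot values double array of per-voxel intensities, finite everywhere.
#' @export
setClass("ScalarImage",
  representation(grid = "ImageGrid", values = "array"),
  validity = function(object) {
    if (!identical(dim(object@values), dim_of(object@grid)))
      return("values dimensions do not match grid shape")
    if (!all(is.finite(object@values))) return("values must be finite")
    TRUE
  })

#' Integer region-of-interest volume
#'
#' Label 0 is reserved for background. `labelNames` maps label ids (as
#' character keys) to ROI names; every nonzero id present in `labels` must
#' be named.
#'
#' @slot grid the [ImageGrid-class].
#' @slot labels integer array of per-voxel labels (>= 0).
#' @slot labelNames named character vector, names are label ids.
#' @export
setClass("LabelImage",
  representation(grid = "ImageGrid", labels = "array",
                 labelNames = "character"),
  validity = function(object) {
    if (!identical(dim(object@labels), dim_of(object@grid)))
      return("labels dimensions do not match grid shape")
    if (!is.integer(object@labels)) return("labels must be integer-typed")
    if (any(object@labels < 0L)) return("labels must be non-negative")
    ids <- setdiff(unique(as.vector(object@labels)), 0L)
    if (length(ids) && !all(as.character(ids) %in% names(object@labelNames)))
      return("every nonzero label id must appear in labelNames")
    TRUE
  })

#' Vector field on an image grid
#'
#' One scalar array per axis; components are expressed in domain units
#' (fractions of the unit cube), not voxels.
#'
#' @slot grid the [ImageGrid-class].
#' @slot components list of double arrays, one per axis.
#' @export
setClass("VectorField",
  representation(grid = "ImageGrid", components = "list"),
  validity = function(object) {
    d <- length(object@grid@shape)
    if (length(object@components) != d)
      return("need one component per grid axis")
    for (c in object@components) {
      if (!identical(dim(c), dim_of(object@grid)))
        return("component dimensions do not match grid shape")
      if (!all(is.finite(c))) return("components must be finite")
    }
    TRUE
  })

#' Grid-sampled map of the unit cube into itself
#'
#' Stored as a displacement from the identity, in domain units: the mapped
#' position of voxel center x is `x + displacement(x)`. A map used to pull
#' back an image samples that image at the mapped positions. A map labelled
#' diffeomorphic must have strictly positive Jacobian determinant at every
#' voxel (see [jacobianDeterminant()]).
#'
#' @slot grid the [ImageGrid-class].
#' @slot displacement list of double arrays, one per axis, domain units.
#' @export
setClass("DeformationMap",
  representation(grid = "ImageGrid", displacement = "list"),
  validity = function(object) {
    d <- length(object@grid@shape)
    if (length(object@displacement) != d)
      return("need one displacement component per grid axis")
    for (c in object@displacement) {
      if (!identical(dim(c), dim_of(object@grid)))
        return("displacement dimensions do not match grid shape")
      if (!all(is.finite(c))) return("displacement must be finite")
    }
    TRUE
  })

#' Parameters of the smoothing operator L
#'
#' L = -alpha * Laplacian + gamma * Id acting componentwise on velocity
#' fields; the induced kernel is K = (L' L)^-1. alpha/gamma in roughly
#' [0.001, 0.05] is the working range for brain-scale deformations: smaller
#' alpha gives more local, more elastic deformations.
#'
#' @slot alpha non-negative smoothness weight.
#' @slot gamma positive zeroth-order weight (default 1).
#' @export
setClass("KernelParams",
  representation(alpha = "numeric", gamma = "numeric"),
  validity = function(object) {
    if (length(object@alpha) != 1 || length(object@gamma) != 1)
      return("alpha and gamma must be scalars")
    if (!is.finite(object@gamma) || object@gamma <= 0)
      return("gamma must be > 0")
    if (!is.finite(object@alpha) || object@alpha < 0)
      return("alpha must be >= 0")
    TRUE
  })

#' Per-frequency multipliers of L and K
#'
#' `A` is the DFT symbol of L under the periodic second-difference
#' Laplacian, `A = gamma + 2 alpha sum_d (1 - cos(2 pi k_d / N_d)) / h_d^2`;
#' `Kmult = 1/A^2` is the symbol of K = (L'L)^-1.
#'
#' @slot grid the [ImageGrid-class].
#' @slot A double array of L multipliers (>= gamma everywhere).
#' @slot Kmult double array, `1/A^2`.
#' @export
setClass("KernelMultipliers",
  representation(grid = "ImageGrid", A = "array", Kmult = "array"),
  validity = function(object) {
    if (!identical(dim(object@A), dim_of(object@grid)) ||
        !identical(dim(object@Kmult), dim_of(object@grid)))
      return("multiplier dimensions do not match grid shape")
    if (any(object@A <= 0)) return("A must be positive everywhere")
    TRUE
  })

#' LDDMM solver parameters
#'
#' @slot kernel a [KernelParams-class] (alpha, gamma).
#' @slot sigma positive mismatch weight (1/sigma^2 scales the image term).
#' @slot nTimeSteps positive integer T; T = 10 is the default, T = 1
#'   approximates the small-deformation (elastic) setting.
#' @slot epsilon0 initial gradient-descent step size.
#' @slot maxIter iteration cap.
#' @slot tol relative total-energy change below which (held for
#'   `tolWindow` iterations) the descent stops.
#' @slot tolWindow number of consecutive small-change iterations required.
#' @slot lineSearch if TRUE (default) backtrack epsilon until the energy
#'   does not increase; FALSE reproduces a fixed-step update.
#' @slot seed integer, recorded for provenance (the solver itself is
#'   deterministic).
#' @export
setClass("LDDMMParams",
  representation(kernel = "KernelParams", sigma = "numeric",
                 nTimeSteps = "integer", epsilon0 = "numeric",
                 maxIter = "integer", tol = "numeric", tolWindow = "integer",
                 lineSearch = "logical", seed = "integer"),
  validity = function(object) {
    if (object@nTimeSteps < 1L) return("nTimeSteps must be >= 1")
    if (!is.finite(object@sigma) || object@sigma <= 0)
      return("sigma must be > 0")
    if (object@epsilon0 <= 0) return("epsilon0 must be > 0")
    if (object@maxIter < 1L) return("maxIter must be >= 1")
    if (object@tol < 0) return("tol must be >= 0")
    TRUE
  })

#' Result of an LDDMM registration
#'
#' @slot phi forward map phi = phi_1 (atlas coordinates flow to target).
#' @slot phiInv backward map phi^-1 = phi_{1,0}; the deformed atlas is the
#'   pullback of the atlas through this map.
#' @slot velocity list of per-timestep [VectorField-class] objects.
#' @slot energyTrace data.frame with one row per accepted iteration:
#'   `iter`, `total`, `reg`, `mismatch`, `stepSize` (and `stage` for
#'   cascades); `total = reg + mismatch` and is non-increasing.
#' @slot converged logical, TRUE if the relative-change criterion fired.
#' @slot iterations accepted iterations used.
#' @slot params the [LDDMMParams-class] used (of the last stage, for
#'   cascades).
#' @slot metricRetained FALSE for cascaded registrations, whose composed
#'   map is no longer a geodesic endpoint of a single flow.
#' @export
setClass("RegistrationResult",
  representation(phi = "DeformationMap", phiInv = "DeformationMap",
                 velocity = "list", energyTrace = "data.frame",
                 converged = "logical", iterations = "integer",
                 params = "LDDMMParams", metricRetained = "logical"))

#' Affine pre-alignment transform
#'
#' Maps atlas (source) domain coordinates x to target coordinates
#' `matrix %*% x + translation`.
#'
#' @slot matrix d x d matrix, invertible.
#' @slot translation length-d vector.
#' @export
setClass("AffineTransform",
  representation(matrix = "matrix", translation = "numeric"),
  validity = function(object) {
    d <- nrow(object@matrix)
    if (ncol(object@matrix) != d || length(object@translation) != d)
      return("matrix must be square and match translation length")
    if (abs(det(object@matrix)) < 1e-12)
      return("matrix must be invertible")
    TRUE
  })

#' One atlas: an intensity image plus its ROI charts
#'
#' @slot image a [ScalarImage-class].
#' @slot labels a [LabelImage-class] on the same grid.
#' @slot id character name of the atlas.
#' @export
setClass("AtlasEntry",
  representation(image = "ScalarImage", labels = "LabelImage",
                 id = "character"),
  validity = function(object) {
    if (!identical(object@image@grid@shape, object@labels@grid@shape))
      return("atlas image and labels must share a grid")
    TRUE
  })

#' Parameters of the EM likelihood fusion
#'
#' @slot noiseVar initial Gaussian likelihood variance (EM-updated); NA
#'   means initialize from the data.
#' @slot maxEmIter EM iteration cap (default 10).
#' @slot emTol relative log-likelihood change tolerance.
#' @slot neighborhoodRadius voxels; 0 (default) weights each voxel by its
#'   own residual, r > 0 averages squared residuals over a (2r+1)^d box
#'   before the exponential.
#' @slot tieBreak label-tie rule; only "smallest" is defined.
#' @export
setClass("FusionParams",
  representation(noiseVar = "numeric", maxEmIter = "integer",
                 emTol = "numeric", neighborhoodRadius = "integer",
                 tieBreak = "character"),
  validity = function(object) {
    if (!is.na(object@noiseVar) && object@noiseVar <= 0)
      return("noiseVar must be > 0")
    if (object@maxEmIter < 1L) return("maxEmIter must be >= 1")
    if (object@neighborhoodRadius < 0L)
      return("neighborhoodRadius must be >= 0")
    if (!object@tieBreak %in% "smallest")
      return("unknown tieBreak rule")
    TRUE
  })

#' Result of multi-atlas likelihood fusion
#'
#' @slot labels fused [LabelImage-class] in subject space.
#' @slot weights list (per atlas) of per-voxel responsibility arrays;
#'   non-negative, summing to 1 at every voxel.
#' @slot mixing per-atlas global priors pi_j (>= 0, sum 1).
#' @slot emTrace per-iteration observed-data log-likelihood,
#'   non-decreasing.
#' @export
setClass("FusionResult",
  representation(labels = "LabelImage", weights = "list",
                 mixing = "numeric", emTrace = "numeric"),
  validity = function(object) {
    if (length(object@weights) != length(object@mixing))
      return("one weight field per atlas required")
    if (any(object@mixing < -1e-12) ||
        abs(sum(object@mixing) - 1) > 1e-8)
      return("mixing proportions must be convex")
    TRUE
  })

#' Specification of a synthetic labeled phantom
#'
#' @slot shape grid extents.
#' @slot structures data.frame with columns `name`, `intensity`, per-axis
#'   centers `c1..cd` and radii `r1..rd` (domain units).
#' @slot backgroundIntensity background level.
#' @slot noiseSd additive Gaussian noise sd (intensity units).
#' @slot seed integer driving all randomness.
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", structures = "data.frame",
                 backgroundIntensity = "numeric", noiseSd = "numeric",
                 seed = "integer"),
  validity = function(object) {
    d <- length(object@shape)
    need <- c("name", "intensity", paste0("c", seq_len(d)),
              paste0("r", seq_len(d)))
    if (!all(need %in% names(object@structures)))
      return(paste("structures must have columns:",
                   paste(need, collapse = ", ")))
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    rad <- as.matrix(object@structures[, paste0("r", seq_len(d))])
    if (any(t(rad) * object@shape <= 1))
      return("all radii must exceed one voxel")
    TRUE
  })

#' A phantom subject with known ground truth
#'
#' @slot image noisy intensity [ScalarImage-class].
#' @slot labels ground-truth [LabelImage-class] (noise-free membership).
#' @slot deformation the known diffeomorphism relating this subject to the
#'   base phantom (the subject is the pullback of the base through it), or
#'   NULL for the base itself.
#' @export
setClass("GroundTruth",
  representation(image = "ScalarImage", labels = "LabelImage",
                 deformation = "ANY"),
  validity = function(object) {
    if (!identical(object@image@grid@shape, object@labels@grid@shape))
      return("image and labels must share a grid")
    if (!is.null(object@deformation) &&
        !is(object@deformation, "DeformationMap"))
      return("deformation must be a DeformationMap or NULL")
    TRUE
  })
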