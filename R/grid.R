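# Grid geometry and core constructors.

# dim() attribute a grid's arrays must carry
dim_of <- function(grid) as.integer(grid@shape)

nVoxels <- function(grid) prod(grid@shape)

voxelVolume <- function(grid) prod(grid@spacing)

gridDim <- function(grid) length(grid@shape)

#' Construct an image grid on the unit cube
#'
#' @param shape integer extents per axis (2 or 3 axes, each >= 4).
#' @param origin corner coordinate, default 0 per axis.
#' @return an [ImageGrid-class] with `spacing = 1/shape`, so voxel centers
#'   lie at `(i - 0.5)/shape` and the domain is `[0,1]^d` exactly.
#' @examples
#' g <- ImageGrid(c(16, 16))
#' @export
ImageGrid <- function(shape, origin = rep(0, length(shape))) {
  shape <- as.integer(shape)
  new("ImageGrid", shape = shape, spacing = 1 / shape,
      origin = as.numeric(origin))
}

#' Construct a scalar image
#'
#' @param values numeric array (or matrix); coerced to double.
#' @param grid an [ImageGrid-class]; defaults to a unit-cube grid matching
#'   `dim(values)`.
#' @return a [ScalarImage-class]
#' @export
ScalarImage <- function(values, grid = ImageGrid(dim(values))) {
  storage.mode(values) <- "double"
  new("ScalarImage", grid = grid, values = values)
}

#' Construct a label image
#'
#' @param labels integer array of per-voxel labels; 0 is background.
#' @param grid an [ImageGrid-class]; defaults to match `dim(labels)`.
#' @param labelNames named character vector mapping label ids to ROI
#'   names; defaults to naming every nonzero id `"roi<k>"`.
#' @return a [LabelImage-class]
#' @export
LabelImage <- function(labels, grid = ImageGrid(dim(labels)),
                       labelNames = NULL) {
  storage.mode(labels) <- "integer"
  if (is.null(labelNames)) {
    ids <- sort(setdiff(unique(as.vector(labels)), 0L))
    labelNames <- stats::setNames(paste0("roi", ids), as.character(ids))
  }
  new("LabelImage", grid = grid, labels = labels, labelNames = labelNames)
}

#' Construct a vector field
#'
#' @param components list of numeric arrays (domain units), one per axis,
#'   or a single scalar to fill every component.
#' @param grid an [ImageGrid-class].
#' @return a [VectorField-class]
#' @export
VectorField <- function(components, grid) {
  if (!is.list(components)) {
    fill <- components
    components <- lapply(seq_along(grid@shape),
                         function(c) array(fill, dim_of(grid)))
  }
  components <- lapply(components, function(a) {
    storage.mode(a) <- "double"; a
  })
  new("VectorField", grid = grid, components = components)
}

#' Construct a deformation map from displacement arrays
#'
#' @param displacement list of numeric arrays (domain units), one per
#'   axis, or a single scalar to fill with.
#' @param grid an [ImageGrid-class].
#' @return a [DeformationMap-class]
#' @export
DeformationMap <- function(displacement, grid) {
  if (!is.list(displacement)) {
    fill <- displacement
    displacement <- lapply(seq_along(grid@shape),
                           function(c) array(fill, dim_of(grid)))
  }
  displacement <- lapply(displacement, function(a) {
    storage.mode(a) <- "double"; a
  })
  new("DeformationMap", grid = grid, displacement = displacement)
}

# Per-axis voxel-center coordinates
axisCenters <- function(grid, axis) {
  grid@origin[axis] + (seq_len(grid@shape[axis]) - 0.5) * grid@spacing[axis]
}

# Array of the `axis` coordinate at every voxel
coordArray <- function(grid, axis) {
  n <- dim_of(grid)
  x <- axisCenters(grid, axis)
  if (axis == 1L) array(rep(x, times = prod(n[-1])), n)
  else if (axis == length(n)) array(rep(x, each = prod(n[-length(n)])), n)
  else array(rep(rep(x, each = n[1]), times = n[3]), n) # middle axis, d = 3
}

# List of coordinate arrays (the identity map's coords)
identityCoords <- function(grid) {
  lapply(seq_along(grid@shape), function(a) coordArray(grid, a))
}

# n x d matrix of every voxel center, column-major voxel order
allVoxelCenters <- function(grid) {
  do.call(cbind, lapply(identityCoords(grid), as.vector))
}

sameGrid <- function(a, b) {
  identical(a@shape, b@shape) &&
    isTRUE(all.equal(a@spacing, b@spacing)) &&
    isTRUE(all.equal(a@origin, b@origin))
}

stopIfGridMismatch <- function(a, b, what = "inputs") {
  if (!sameGrid(a, b)) stop(what, " must share the same grid", call. = FALSE)
  invisible(TRUE)
}

# Extract along one axis with an index vector, other axes untouched.
indexAxis <- function(arr, axis, idx) {
  args <- rep(list(TRUE), length(dim(arr)))
  args[[axis]] <- idx
  do.call(`[`, c(list(arr), args, list(drop = FALSE)))
}

setMethod("show", "ImageGrid", function(object) {
  cat("ImageGrid:", paste(object@shape, collapse = " x "),
      "voxels on [0,1]^", gridDim(object), "\n", sep = "")
})

setMethod("show", "ScalarImage", function(object) {
  cat("ScalarImage: ", paste(object@grid@shape, collapse = " x "),
      ", range [", signif(min(object@values), 4), ", ",
      signif(max(object@values), 4), "]\n", sep = "")
})

setMethod("show", "LabelImage", function(object) {
  ids <- sort(setdiff(unique(as.vector(object@labels)), 0L))
  cat("LabelImage: ", paste(object@grid@shape, collapse = " x "),
      ", ", length(ids), " ROI(s)\n", sep = "")
})

setMethod("show", "DeformationMap", function(object) {
  mx <- max(vapply(object@displacement,
                   function(a) max(abs(a)), numeric(1)))
  cat("DeformationMap: ", paste(object@grid@shape, collapse = " x "),
      ", max |displacement| = ", signif(mx, 4), " (domain units)\n",
      sep = "")
})

setMethod("show", "RegistrationResult", function(object) {
  n <- nrow(object@energyTrace)
  cat("RegistrationResult: ", object@iterations, " iteration(s), ",
      if (object@converged) "converged" else "iteration cap reached",
      "\n  final energy: total = ",
      signif(object@energyTrace$total[n], 6),
      " (reg = ", signif(object@energyTrace$reg[n], 6),
      ", mismatch = ", signif(object@energyTrace$mismatch[n], 6), ")\n",
      if (!object@metricRetained)
        "  cascaded map: metric property not retained\n" else "",
      sep = "")
})

setMethod("show", "FusionResult", function(object) {
  cat("FusionResult: ", length(object@weights), " atlas(es), ",
      length(object@emTrace), " EM iteration(s), final log-lik = ",
      signif(object@emTrace[length(object@emTrace)], 6), "\n", sep = "")
})
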