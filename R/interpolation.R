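# Multilinear and nearest-neighbor sampling with boundary clamping.
#
# All sampling clamps out-of-domain coordinates onto the boundary; the
# phantoms have uniform background so clamping introduces no artifacts and
# avoids the wrap-around that the periodic smoothing kernel would imply.

# Domain points (n x d matrix) -> fractional 1-based voxel indices,
# clamped into [1, N_d].
pointsToIndex <- function(grid, points) {
  points <- as.matrix(points)
  if (!all(is.finite(points)))
    stop("sample points must be finite", call. = FALSE)
  d <- gridDim(grid)
  if (ncol(points) != d)
    stop("points must have one column per grid axis", call. = FALSE)
  U <- matrix(0, nrow(points), d)
  for (a in seq_len(d)) {
    u <- (points[, a] - grid@origin[a]) / grid@spacing[a] + 0.5
    U[, a] <- pmin(pmax(u, 1), grid@shape[a])
  }
  U
}

# Multilinear interpolation of `arr` at fractional indices U (n x d).
# Unrolled per dimension; this is the innermost loop of the solver.
interpAtIndex <- function(arr, U) {
  n <- dim(arr)
  if (length(n) == 2L) {
    u <- pmin.int(pmax.int(U[, 1L], 1), n[1L])
    v <- pmin.int(pmax.int(U[, 2L], 1), n[2L])
    i0 <- pmin.int(floor(u), n[1L] - 1)
    j0 <- pmin.int(floor(v), n[2L] - 1)
    fu <- u - i0
    fv <- v - j0
    base <- i0 + (j0 - 1) * n[1L]
    (1 - fv) * ((1 - fu) * arr[base] + fu * arr[base + 1]) +
      fv * ((1 - fu) * arr[base + n[1L]] + fu * arr[base + n[1L] + 1])
  } else {
    u <- pmin.int(pmax.int(U[, 1L], 1), n[1L])
    v <- pmin.int(pmax.int(U[, 2L], 1), n[2L])
    w <- pmin.int(pmax.int(U[, 3L], 1), n[3L])
    i0 <- pmin.int(floor(u), n[1L] - 1)
    j0 <- pmin.int(floor(v), n[2L] - 1)
    k0 <- pmin.int(floor(w), n[3L] - 1)
    fu <- u - i0
    fv <- v - j0
    fw <- w - k0
    s2 <- n[1L]
    s3 <- n[1L] * n[2L]
    base <- i0 + (j0 - 1) * s2 + (k0 - 1) * s3
    c00 <- (1 - fu) * arr[base] + fu * arr[base + 1]
    c10 <- (1 - fu) * arr[base + s2] + fu * arr[base + s2 + 1]
    c01 <- (1 - fu) * arr[base + s3] + fu * arr[base + s3 + 1]
    c11 <- (1 - fu) * arr[base + s2 + s3] + fu * arr[base + s2 + s3 + 1]
    (1 - fw) * ((1 - fv) * c00 + fv * c10) +
      fw * ((1 - fv) * c01 + fv * c11)
  }
}

nearestAtIndex <- function(arr, U) {
  n <- dim(arr)
  idx <- round(pmin.int(pmax.int(U[, 1L], 1), n[1L]))
  s <- n[1L]
  idx <- idx + (round(pmin.int(pmax.int(U[, 2L], 1), n[2L])) - 1) * s
  if (length(n) == 3L) {
    s <- s * n[2L]
    idx <- idx + (round(pmin.int(pmax.int(U[, 3L], 1), n[3L])) - 1) * s
  }
  arr[idx]
}

#' Sample a scalar image at arbitrary domain points
#'
#' Multilinear (bilinear / trilinear) interpolation of the voxel-center
#' values. Exact at voxel centers and for images that are affine functions
#' of the coordinates; points outside the domain are clamped onto it.
#'
#' @param image a [ScalarImage-class].
#' @param points n x d matrix of domain coordinates in `[0,1]^d`.
#' @return numeric vector of n interpolated values
#' @export
sampleLinear <- function(image, points) {
  interpAtIndex(image@values, pointsToIndex(image@grid, points))
}

#' Sample a label image at arbitrary domain points
#'
#' Nearest-voxel-center lookup, so labels stay integral and the output
#' alphabet is a subset of the input alphabet.
#'
#' @param labels a [LabelImage-class].
#' @param points n x d matrix of domain coordinates.
#' @return integer vector of n labels
#' @export
sampleNearest <- function(labels, points) {
  nearestAtIndex(labels@labels, pointsToIndex(labels@grid, points))
}

# Fractional sample indices of a map's targets: identity index + disp/h.
mapSampleIndex <- function(map) {
  grid <- map@grid
  n <- dim_of(grid)
  d <- length(n)
  U <- matrix(0, prod(n), d)
  for (a in seq_len(d)) {
    base <- if (a == 1L) rep(seq_len(n[1]), times = prod(n[-1]))
      else if (a == d) rep(seq_len(n[a]), each = prod(n[-d]))
      else rep(rep(seq_len(n[2]), each = n[1]), times = n[3])
    U[, a] <- base + as.vector(map@displacement[[a]]) / grid@spacing[a]
  }
  U
}

#' Pull back a scalar image through a deformation map
#'
#' Returns the image `I . phi` on the map's grid, i.e. the image sampled
#' (multilinearly) at the mapped positions `phi(x)` of every voxel center
#' x. The image may live on a different grid of the same unit-cube
#' domain; when the grids coincide the fast index path is used, keeping
#' composition with the identity exact.
#'
#' @param image a [ScalarImage-class].
#' @param map a [DeformationMap-class].
#' @return a [ScalarImage-class] on the map's grid
#' @export
warpImage <- function(image, map) {
  vals <- if (sameGrid(image@grid, map@grid)) {
    interpAtIndex(image@values, mapSampleIndex(map))
  } else {
    pts <- do.call(cbind, lapply(mapCoords(map), as.vector))
    sampleLinear(image, pts)
  }
  ScalarImage(array(vals, dim_of(map@grid)), map@grid)
}

#' Pull back a label image through a deformation map
#'
#' Nearest-neighbor pullback: voxel x receives the label at the voxel
#' center nearest to `phi(x)`. The label alphabet is preserved.
#'
#' @param labels a [LabelImage-class].
#' @param map a [DeformationMap-class].
#' @return a [LabelImage-class] on the map's grid
#' @export
warpLabels <- function(labels, map) {
  vals <- if (sameGrid(labels@grid, map@grid)) {
    nearestAtIndex(labels@labels, mapSampleIndex(map))
  } else {
    pts <- do.call(cbind, lapply(mapCoords(map), as.vector))
    sampleNearest(labels, pts)
  }
  LabelImage(array(as.integer(vals), dim_of(map@grid)), map@grid,
             labelNames = labels@labelNames)
}
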