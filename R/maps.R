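# Map algebra and differential operators.

#' Identity deformation map
#'
#' @param grid an [ImageGrid-class].
#' @return a [DeformationMap-class] with exactly zero displacement
#' @export
identityMap <- function(grid) DeformationMap(0, grid)

#' Compose two deformation maps
#'
#' Returns the map `x -> outer(inner(x))`. The outer map's displacement is
#' evaluated at the inner map's targets by multilinear interpolation;
#' composition with the identity (on either side) is exact on the stored
#' displacement.
#'
#' @param outer,inner [DeformationMap-class] objects on the same grid.
#' @return a [DeformationMap-class]
#' @export
composeMaps <- function(outer, inner) {
  stopIfGridMismatch(outer@grid, inner@grid, "composed maps")
  grid <- outer@grid
  U <- mapSampleIndex(inner)
  disp <- lapply(seq_len(gridDim(grid)), function(c) {
    inner@displacement[[c]] +
      array(interpAtIndex(outer@displacement[[c]], U), dim_of(grid))
  })
  DeformationMap(disp, grid)
}

# Finite-difference derivative of an array along one axis, divided by the
# grid spacing: central in the interior, one-sided at the boundary.
fdDeriv <- function(arr, grid, axis) {
  n <- dim(arr)[axis]
  ip <- pmin(seq_len(n) + 1L, n)
  im <- pmax(seq_len(n) - 1L, 1L)
  num <- indexAxis(arr, axis, ip) - indexAxis(arr, axis, im)
  den <- (ip - im) * grid@spacing[axis]
  sweep(num, axis, den, "/")
}

#' Spatial gradient of a scalar image
#'
#' Second-order central differences in the interior, first-order one-sided
#' differences at the boundary, scaled by 1/spacing.
#'
#' @param image a [ScalarImage-class].
#' @return a [VectorField-class] holding the per-axis derivatives
#' @export
spatialGradient <- function(image) {
  comps <- lapply(seq_along(image@grid@shape),
                  function(a) fdDeriv(image@values, image@grid, a))
  VectorField(comps, image@grid)
}

#' Jacobian determinant of a deformation map
#'
#' Central-difference Jacobian of the mapped coordinates (one-sided at the
#' boundary), with its determinant taken voxelwise. A diffeomorphic map
#' has strictly positive determinant everywhere; the identity has
#' determinant exactly 1.
#'
#' @param map a [DeformationMap-class].
#' @return a [ScalarImage-class] of per-voxel determinants
#' @export
jacobianDeterminant <- function(map) {
  grid <- map@grid
  d <- gridDim(grid)
  coords <- mapCoords(map)
  J <- vector("list", d)
  for (c in seq_len(d)) {
    J[[c]] <- lapply(seq_len(d), function(a) fdDeriv(coords[[c]], grid, a))
  }
  det <- if (d == 2L) {
    J[[1]][[1]] * J[[2]][[2]] - J[[1]][[2]] * J[[2]][[1]]
  } else {
    J[[1]][[1]] * (J[[2]][[2]] * J[[3]][[3]] - J[[2]][[3]] * J[[3]][[2]]) -
    J[[1]][[2]] * (J[[2]][[1]] * J[[3]][[3]] - J[[2]][[3]] * J[[3]][[1]]) +
    J[[1]][[3]] * (J[[2]][[1]] * J[[3]][[2]] - J[[2]][[2]] * J[[3]][[1]])
  }
  ScalarImage(det, grid)
}

#' Numerically invert a deformation map
#'
#' Fixed-point iteration for the inverse displacement,
#' `u_inv(x) <- -u(x + u_inv(x))`, which converges for moderate
#' deformations (contraction when the displacement gradient is < 1).
#'
#' @param map a [DeformationMap-class].
#' @param iterations fixed-point iterations (default 30).
#' @return a [DeformationMap-class] approximating `map^-1`
#' @export
invertMap <- function(map, iterations = 30L) {
  grid <- map@grid
  inv <- identityMap(grid)
  for (k in seq_len(iterations)) {
    U <- mapSampleIndex(inv)
    disp <- lapply(seq_len(gridDim(grid)), function(c) {
      -array(interpAtIndex(map@displacement[[c]], U), dim_of(grid))
    })
    inv <- DeformationMap(disp, grid)
  }
  inv
}

# Max |displacement| in voxel units (uses the finest axis spacing).
maxDisplacementVoxels <- function(map) {
  mx <- 0
  for (c in seq_along(map@displacement)) {
    mx <- max(mx, max(abs(map@displacement[[c]])) / map@grid@spacing[c])
  }
  mx
}
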