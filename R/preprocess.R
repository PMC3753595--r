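# Intensity and pose normalization applied before registration.

#' Construct an affine pre-alignment transform
#'
#' @param matrix d x d invertible matrix.
#' @param translation length-d vector.
#' @return an [AffineTransform-class] mapping source coordinates x to
#'   `matrix %*% x + translation`
#' @export
AffineTransform <- function(matrix, translation) {
  new("AffineTransform", matrix = matrix,
      translation = as.numeric(translation))
}

#' Monotone histogram matching
#'
#' Remaps the source intensities so that their quantiles (piecewise
#' linear between `nQuantiles` anchors) equal the reference's. The output
#' minimum and maximum equal the reference's; matching an image to itself
#' (or any monotone increasing rescaling of the reference to the
#' reference) recovers the reference up to quantile-grid resolution, and
#' the operation is idempotent.
#'
#' @param source,reference [ScalarImage-class] objects (grids may
#'   differ).
#' @param nQuantiles number of quantile anchors (default 256).
#' @return a [ScalarImage-class] on the source grid
#' @export
histogramMatch <- function(source, reference, nQuantiles = 256L) {
  stopifnot(nQuantiles >= 2L)
  refv <- as.vector(reference@values)
  if (max(refv) - min(refv) < .Machine$double.eps)
    stop("reference image is constant; quantile map undefined",
         call. = FALSE)
  p <- seq(0, 1, length.out = nQuantiles)
  qs <- stats::quantile(as.vector(source@values), p, names = FALSE)
  qr <- stats::quantile(refv, p, names = FALSE)
  # collapse duplicated source anchors so approx() gets a function
  keep <- !duplicated(qs)
  qs <- qs[keep]; qr <- qr[keep]
  mapped <- if (length(qs) == 1L) rep(qr, length(source@values))
    else stats::approx(qs, qr, xout = as.vector(source@values),
                       rule = 2)$y
  ScalarImage(array(mapped, dim(source@values)), source@grid)
}

# Intensity centroid and second central moments; mass is intensity above
# the per-image minimum so a uniform background carries no weight.
imageMoments <- function(image) {
  w <- as.vector(image@values) - min(image@values)
  tot <- sum(w)
  if (tot <= 0) stop("image has zero intensity mass", call. = FALSE)
  X <- allVoxelCenters(image@grid)
  ctr <- colSums(X * w) / tot
  m2 <- colSums(sweep(X, 2, ctr)^2 * w) / tot
  list(center = ctr, m2 = m2)
}

#' Moment-based affine pre-alignment
#'
#' Matches the intensity centroid and per-axis second central moments of
#' the source to the reference: a diagonal scaling
#' `s_d = sqrt(m2_ref / m2_src)` about the source centroid followed by a
#' translation onto the reference centroid. This stands in for the
#' rigid/affine initialization that precedes the diffeomorphic
#' registration; it is inverse-consistent for pure translations.
#'
#' @param source,reference [ScalarImage-class] objects with positive
#'   intensity mass (intensity above each image's minimum is used as
#'   mass, so a uniform background does not bias the moments).
#' @return an [AffineTransform-class] mapping source coordinates to
#'   reference coordinates
#' @export
momentPrealign <- function(source, reference) {
  ms <- imageMoments(source)
  mr <- imageMoments(reference)
  s <- sqrt(mr$m2 / ms$m2)
  M <- diag(s, length(s))
  t <- mr$center - s * ms$center
  AffineTransform(M, t)
}

#' Resample an image through the inverse of an affine transform
#'
#' Produces the source image expressed in reference coordinates: the
#' output at x is the source sampled at `A^-1(x)`.
#'
#' @param image source [ScalarImage-class].
#' @param affine an [AffineTransform-class] from source to reference
#'   coordinates.
#' @param grid output [ImageGrid-class] (default: the source grid).
#' @return a [ScalarImage-class] on `grid`
#' @export
applyAffine <- function(image, affine, grid = image@grid) {
  Minv <- solve(affine@matrix)
  X <- allVoxelCenters(grid)
  src <- sweep(X, 2, affine@translation) %*% t(Minv)
  ScalarImage(array(sampleLinear(image, src), dim_of(grid)), grid)
}

# Compose the affine's inverse after a deformation map: the returned map
# sends x -> A^-1(phi(x)), i.e. the pullback map from reference space all
# the way into source (atlas) space.
composeAffineInvWithMap <- function(affine, map) {
  grid <- map@grid
  Minv <- solve(affine@matrix)
  coords <- mapCoords(map)
  X <- do.call(cbind, lapply(coords, as.vector))
  src <- sweep(X, 2, affine@translation) %*% t(Minv)
  ident <- identityCoords(grid)
  disp <- lapply(seq_len(gridDim(grid)), function(c) {
    array(src[, c], dim_of(grid)) - ident[[c]]
  })
  DeformationMap(disp, grid)
}
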