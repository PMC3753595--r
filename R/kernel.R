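# The operator L = -alpha Laplacian + gamma Id and its induced kernel
# K = (L'L)^-1, applied in the Fourier domain.
#
# The Laplacian is the periodic second-difference stencil, whose DFT
# eigenvalues along one axis are 2(1 - cos(2 pi k / N)) / h^2.  With that
# discretization L is real, diagonal in frequency and self-adjoint, so
# L'L = L^2 and the kernel multiplier is A(w)^-2.

#' Construct kernel parameters
#'
#' @param alpha non-negative smoothness weight; alpha/gamma in roughly
#'   0.001-0.05 is the working range, smaller alpha giving more local and
#'   elastic deformations.
#' @param gamma positive zeroth-order weight, default 1.
#' @return a [KernelParams-class]
#' @export
KernelParams <- function(alpha, gamma = 1) {
  new("KernelParams", alpha = as.numeric(alpha), gamma = as.numeric(gamma))
}

# Per-axis DFT eigenvalues of the periodic second-difference Laplacian.
laplacianEigenvalues <- function(grid, axis) {
  n <- grid@shape[axis]
  h <- grid@spacing[axis]
  2 * (1 - cos(2 * pi * (seq_len(n) - 1) / n)) / h^2
}

#' Build the per-frequency multipliers of L and K
#'
#' `A(w) = gamma + alpha * sum_d lambda_d(w)` with `lambda_d` the periodic
#' second-difference Laplacian eigenvalues; `Kmult = 1/A^2`. At zero
#' frequency `A = gamma` exactly; with `alpha = 0`, `A` is identically
#' gamma and K degenerates to `Id / gamma^2`.
#'
#' @param grid an [ImageGrid-class].
#' @param params a [KernelParams-class].
#' @return a [KernelMultipliers-class]
#' @export
buildMultipliers <- function(grid, params) {
  stopifnot(is(params, "KernelParams"))
  A <- array(params@gamma, dim_of(grid))
  for (a in seq_along(grid@shape)) {
    A <- sweep(A, a, params@alpha * laplacianEigenvalues(grid, a), "+")
  }
  new("KernelMultipliers", grid = grid, A = A, Kmult = 1 / A^2)
}

fftApplyMult <- function(arr, mult) {
  Re(stats::fft(stats::fft(arr) * mult, inverse = TRUE)) / length(arr)
}

#' Apply the smoothing kernel K = (L'L)^-1 to a vector field
#'
#' Each component is transformed with the DFT, multiplied by the kernel
#' multiplier and transformed back. K is a low-pass filter; a constant
#' field c maps to c/gamma^2.
#'
#' @param field a [VectorField-class].
#' @param mult a [KernelMultipliers-class] on the same grid.
#' @return a [VectorField-class]
#' @export
applyK <- function(field, mult) {
  stopIfGridMismatch(field@grid, mult@grid, "field and multipliers")
  comps <- lapply(field@components, fftApplyMult, mult = mult@Kmult)
  VectorField(comps, field@grid)
}

#' Apply the operator L to a vector field (stencil form)
#'
#' `L v = -alpha * Laplacian(v) + gamma * v` per component, with the
#' periodic second-difference Laplacian. Agrees with the Fourier form
#' (multiplication by `A`) to round-off; a constant field maps to
#' `gamma * field` and DFT modes are eigenfunctions with eigenvalue
#' `A(w)`.
#'
#' @param field a [VectorField-class].
#' @param params a [KernelParams-class].
#' @return a [VectorField-class]
#' @export
applyL <- function(field, params) {
  grid <- field@grid
  comps <- lapply(field@components, function(arr) {
    lap <- array(0, dim(arr))
    for (a in seq_along(grid@shape)) {
      n <- dim(arr)[a]
      ip <- c(seq_len(n)[-1], 1L)       # periodic +1
      im <- c(n, seq_len(n)[-n])        # periodic -1
      lap <- lap + (indexAxis(arr, a, ip) + indexAxis(arr, a, im) -
                    2 * arr) / grid@spacing[a]^2
    }
    params@gamma * arr - params@alpha * lap
  })
  VectorField(comps, grid)
}

# Fourier form of L, used as the dual-implementation cross-check and to
# evaluate ||L v||^2 without a second stencil pass.
applyLFourier <- function(field, mult) {
  comps <- lapply(field@components, fftApplyMult, mult = mult@A)
  VectorField(comps, field@grid)
}
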