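# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately naive (loops, dense matrices, explicit
# set operations) and independent of the package's vectorized paths.

# ---- fixtures ------------------------------------------------------------

gridCoords1 <- function(n) (seq_len(n) - 0.5) / n

# Sum-of-Gaussian-bumps image tapered to exactly zero within ~3 voxels
# of the boundary (so clamped sampling never sees a nonzero integrand),
# on a 2-D grid. Bumps are kept wide relative to the voxel size so that
# finite differences resolve them.
interiorBumps <- function(n, seed, k = 3) {
  set.seed(seed)
  x <- gridCoords1(n)
  a <- array(0, c(n, n))
  for (i in seq_len(k)) {
    cx <- runif(1, 0.35, 0.65); cy <- runif(1, 0.35, 0.65)
    s <- runif(1, 0.06, 0.12); amp <- runif(1, 0.5, 1)
    a <- a + amp * outer(x, x, function(u, v)
      exp(-((u - cx)^2 + (v - cy)^2) / (2 * s^2)))
  }
  m <- 3 / n
  taper <- function(t) {
    z <- pmin(pmax((pmin(t, 1 - t) - m) / m, 0), 1)
    z * z * (3 - 2 * z)   # smoothstep, exactly 0 inside the margin
  }
  w <- outer(taper(x), taper(x))
  ScalarImage(a * w, ImageGrid(c(n, n)))
}

blobImage <- function(n, cx, cy, s = 0.08) {
  x <- gridCoords1(n)
  ScalarImage(outer(x, x, function(u, v)
    exp(-((u - cx)^2 + (v - cy)^2) / (2 * s^2))), ImageGrid(c(n, n)))
}

# Smooth random velocity direction (kernel-smoothed white noise).
smoothDirection <- function(grid, mult, seed) {
  set.seed(seed)
  dims <- dim(displacement(identityMap(grid))[[1]])
  noise <- VectorField(lapply(seq_along(dims), function(c)
    array(rnorm(prod(dims)), dims)), grid)
  applyK(noise, mult)
}

# ---- dense kernel oracle -------------------------------------------------

# Dense periodic 1-D operator L = -alpha * second-difference/h^2 + gamma.
denseL1D <- function(n, alpha, gamma) {
  h <- 1 / n
  L <- diag(gamma + 2 * alpha / h^2, n)
  for (i in seq_len(n)) {
    ip <- if (i == n) 1L else i + 1L
    im <- if (i == 1L) n else i - 1L
    L[i, ip] <- L[i, ip] - alpha / h^2
    L[i, im] <- L[i, im] - alpha / h^2
  }
  L
}

# Dense periodic 2-D operator on an n x n grid, voxels in column-major
# order (matching as.vector of an array).
denseL2D <- function(n, alpha, gamma) {
  h <- 1 / n
  N <- n * n
  L <- matrix(0, N, N)
  idx <- function(i, j) i + (j - 1L) * n
  wrap <- function(i) ((i - 1L) %% n) + 1L
  for (j in seq_len(n)) for (i in seq_len(n)) {
    p <- idx(i, j)
    L[p, p] <- L[p, p] + gamma + 4 * alpha / h^2
    for (nb in list(c(wrap(i + 1L), j), c(wrap(i - 1L), j),
                    c(i, wrap(j + 1L)), c(i, wrap(j - 1L)))) {
      q <- idx(nb[1], nb[2])
      L[p, q] <- L[p, q] - alpha / h^2
    }
  }
  L
}

# Matrix of the package's Fourier-domain K on an n x n grid, built by
# applying it to every unit vector.
fourierKMatrix2D <- function(n, params) {
  g <- ImageGrid(c(n, n))
  mult <- buildMultipliers(g, params)
  N <- n * n
  K <- matrix(0, N, N)
  zero <- array(0, c(n, n))
  for (p in seq_len(N)) {
    e <- zero
    e[p] <- 1
    out <- applyK(VectorField(list(e, e), g), mult)
    K[, p] <- as.vector(fieldComponents(out)[[1]])
  }
  K
}

# ---- naive interpolation oracle -----------------------------------------

# Scalar bilinear interpolation at one domain point, clamped, written
# straight from the definition.
naiveBilinear <- function(arr, pt) {
  n <- dim(arr)
  u <- min(max(pt[1] * n[1] + 0.5, 1), n[1])
  v <- min(max(pt[2] * n[2] + 0.5, 1), n[2])
  i0 <- min(max(floor(u), 1), n[1] - 1)
  j0 <- min(max(floor(v), 1), n[2] - 1)
  fu <- u - i0; fv <- v - j0
  (1 - fu) * (1 - fv) * arr[i0, j0] + fu * (1 - fv) * arr[i0 + 1, j0] +
    (1 - fu) * fv * arr[i0, j0 + 1] + fu * fv * arr[i0 + 1, j0 + 1]
}

# ---- brute-force metrics -------------------------------------------------

bruteKappa <- function(A, M) {
  A <- as.logical(A); M <- as.logical(M)
  n <- length(A)
  tab <- c(sum(A & M), sum(A & !M), sum(!A & M), sum(!A & !M))
  pAgree <- (tab[1] + tab[4]) / n
  fA <- sum(A) / n; fM <- sum(M) / n
  pRandom <- fA * fM + (1 - fA) * (1 - fM)
  (pAgree - pRandom) / (1 - pRandom)
}

bruteVD <- function(A, M) 100 * abs(sum(A) - sum(M)) / sum(M)

bruteL1 <- function(A, M) {
  a <- which(as.logical(A)); m <- which(as.logical(M))
  u <- length(union(a, m)); i <- length(intersect(a, m))
  (u - i) / (u / 2)
}

# ---- small phantom specs -------------------------------------------------

# Two well-separated structures; quick to generate and register.
tinySpec <- function(n = 32, noiseSd = 0.02, seed = 1L) {
  PhantomSpec(c(n, n), data.frame(
    name = c("blobA", "blobB"),
    intensity = c(0.8, 0.5),
    c1 = c(0.35, 0.68), c2 = c(0.40, 0.66),
    r1 = c(0.16, 0.12), r2 = c(0.13, 0.14)),
    noiseSd = noiseSd, seed = seed)
}

expectDiffeomorphic <- function(map) {
  expect_gt(min(intensities(jacobianDeterminant(map))), 0)
}

expectMonotoneTrace <- function(trace) {
  for (s in unique(trace$stage)) {
    tt <- trace$total[trace$stage == s]
    expect_true(all(diff(tt) <= 1e-10 * pmax(abs(tt[-length(tt)]), 1)))
  }
}
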