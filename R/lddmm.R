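# Greedy LDDMM: energy, flow integration, analytic gradient, gradient
# descent with backtracking line search, and the cascading-alpha scheme.
#
# The registration estimates a time-dependent velocity field v_t,
# t = 0..T-1, whose flow phi solves dphi/dt = v_t(phi_t), phi_0 = Id, by
# minimizing
#
#   E(v) = int_0^1 ||L v_t||^2 dt  +  (1/sigma^2) ||I0 . phi^-1 - I1||^2
#
# with L = -alpha Laplacian + gamma Id.  The gradient in the smooth
# velocity space is
#
#   grad_t = 2 v_t - K * ( (2/sigma^2) |D phi_{t,1}| (J0_t - J1_t) grad J0_t )
#
# with J0_t = I0 . phi_{t,0}, J1_t = I1 . phi_{t,1} and K = (L'L)^-1.

#' Construct LDDMM solver parameters
#'
#' @param alpha,gamma smoothing-operator weights (see [KernelParams()]);
#'   defaults alpha = 0.01, gamma = 1.
#' @param sigma mismatch weight; the image term is scaled by 1/sigma^2.
#' @param nTimeSteps number of timesteps T discretizing the flow
#'   (default 10); T = 1 approximates the small-deformation setting.
#' @param epsilon0 initial step size for the velocity update (default 1,
#'   shrunk by the line search as needed).
#' @param maxIter gradient-descent iteration cap (default 100).
#' @param tol relative total-energy change under which, sustained for
#'   `tolWindow` iterations, the descent stops (default 1e-6).
#' @param tolWindow consecutive small-change iterations required
#'   (default 5).
#' @param lineSearch backtrack the step size until the energy does not
#'   increase (default TRUE); FALSE gives the fixed-step update.
#' @param seed integer recorded for provenance.
#' @return an [LDDMMParams-class]
#' @export
LDDMMParams <- function(alpha = 0.01, gamma = 1, sigma = 0.1,
                        nTimeSteps = 10L, epsilon0 = 1, maxIter = 100L,
                        tol = 1e-6, tolWindow = 5L, lineSearch = TRUE,
                        seed = 1L) {
  new("LDDMMParams", kernel = KernelParams(alpha, gamma),
      sigma = as.numeric(sigma), nTimeSteps = as.integer(nTimeSteps),
      epsilon0 = as.numeric(epsilon0), maxIter = as.integer(maxIter),
      tol = as.numeric(tol), tolWindow = as.integer(tolWindow),
      lineSearch = isTRUE(lineSearch), seed = as.integer(seed))
}

# Zero velocity: list of T zero VectorFields.
zeroVelocity <- function(grid, nTimeSteps) {
  lapply(seq_len(nTimeSteps), function(t) VectorField(0, grid))
}

#' Integrate a time-discretized velocity field into its flow maps
#'
#' First-order semi-Lagrangian stepping with dt = 1/T:
#' `phi_{t+dt,0} = phi_{t,0} . (Id - dt v_t)` forward and
#' `phi_{t,1} = phi_{t+dt,1} . (Id + dt v_t)` backward, so the backward
#' maps need no numerical inversion. With `v = 0` every map is the
#' identity; with T = 1 the backward map is `Id - v_0` after a single
#' composition (the small-deformation approximation).
#'
#' @param velocity list of T [VectorField-class] objects on one grid.
#' @return a flow state: list with `phi_t0` and `phi_t1` (each T+1 maps,
#'   entry t holding the map at time (t-1)/T), `phi` (the forward map
#'   phi_1) and `phiInv` (phi_1^-1, used to pull the atlas to the target)
#' @export
integrateFlow <- function(velocity) {
  T <- length(velocity)
  stopifnot(T >= 1L)
  grid <- velocity[[1]]@grid
  for (v in velocity) stopIfGridMismatch(grid, v@grid, "velocity fields")
  dt <- 1 / T
  phi_t0 <- vector("list", T + 1L)
  phi_t1 <- vector("list", T + 1L)
  phi_t0[[1L]] <- identityMap(grid)
  for (t in seq_len(T)) {
    step <- DeformationMap(lapply(velocity[[t]]@components,
                                  function(c) -dt * c), grid)
    phi_t0[[t + 1L]] <- composeMaps(phi_t0[[t]], step)
  }
  phi_t1[[T + 1L]] <- identityMap(grid)
  for (t in rev(seq_len(T))) {
    step <- DeformationMap(lapply(velocity[[t]]@components,
                                  function(c) dt * c), grid)
    phi_t1[[t]] <- composeMaps(phi_t1[[t + 1L]], step)
  }
  list(phi_t0 = phi_t0, phi_t1 = phi_t1,
       phi = phi_t1[[1L]], phiInv = phi_t0[[T + 1L]])
}

#' Evaluate the LDDMM energy of a flow state
#'
#' `reg = dt * sum_t ||L v_t||^2` (voxel-volume-weighted sums of squares,
#' L applied in the Fourier domain) and
#' `mismatch = (1/sigma^2) ||I0 . phi^-1 - I1||^2`.
#'
#' @param flow a flow state from [integrateFlow()].
#' @param velocity the velocity list the state was integrated from.
#' @param I0,I1 atlas and target [ScalarImage-class] objects.
#' @param params an [LDDMMParams-class].
#' @param mult optional precomputed [KernelMultipliers-class].
#' @return named numeric: `total`, `reg`, `mismatch` (total = reg +
#'   mismatch)
#' @export
computeEnergy <- function(flow, velocity, I0, I1, params,
                          mult = buildMultipliers(I0@grid, params@kernel)) {
  grid <- I0@grid
  stopIfGridMismatch(grid, I1@grid, "atlas and target")
  vol <- voxelVolume(grid)
  dt <- 1 / length(velocity)
  reg <- 0
  for (v in velocity) {
    Lv <- applyLFourier(v, mult)
    reg <- reg + dt * vol *
      sum(vapply(Lv@components, function(c) sum(c^2), numeric(1)))
  }
  resid <- warpImage(I0, flow$phiInv)@values - I1@values
  mismatch <- vol * sum(resid^2) / params@sigma^2
  c(total = reg + mismatch, reg = reg, mismatch = mismatch)
}

#' Analytic LDDMM gradient (smoothed, per timestep)
#'
#' For each timestep t:
#' `g_t = 2 v_t - K( (2/sigma^2) |D phi_{t,1}| (J0_t - J1_t) grad J0_t )`
#' with the pullbacks `J0_t = I0 . phi_{t,0}`, `J1_t = I1 . phi_{t,1}`.
#' At a stationary point (I0 = I1, v = 0) the gradient vanishes.
#'
#' @inheritParams computeEnergy
#' @return list of T [VectorField-class] gradients
#' @export
computeGradient <- function(flow, velocity, I0, I1, params,
                            mult = buildMultipliers(I0@grid,
                                                    params@kernel)) {
  grid <- I0@grid
  T <- length(velocity)
  out <- vector("list", T)
  for (t in seq_len(T)) {
    J0 <- warpImage(I0, flow$phi_t0[[t]])
    J1 <- warpImage(I1, flow$phi_t1[[t]])
    detD <- jacobianDeterminant(flow$phi_t1[[t]])@values
    gJ0 <- spatialGradient(J0)
    scal <- (2 / params@sigma^2) * detD * (J0@values - J1@values)
    body <- VectorField(lapply(gJ0@components, function(c) scal * c), grid)
    Kbody <- applyK(body, mult)
    out[[t]] <- VectorField(
      lapply(seq_len(gridDim(grid)), function(c) {
        2 * velocity[[t]]@components[[c]] - Kbody@components[[c]]
      }), grid)
  }
  out
}

#' Inner product of two per-timestep velocity perturbations in V
#'
#' The smooth-velocity-space inner product
#' `<u, w>_V = dt * sum_t vol * sum_x <L u_t, L w_t>`, the product in
#' which [computeGradient()] is the energy gradient: the directional
#' derivative of the energy along w equals `<grad, w>_V`.
#'
#' @param u,w lists of T [VectorField-class] objects.
#' @param mult a [KernelMultipliers-class] for the L being used.
#' @return scalar inner product
#' @export
flowInnerProduct <- function(u, w, mult) {
  stopifnot(length(u) == length(w))
  vol <- voxelVolume(mult@grid)
  dt <- 1 / length(u)
  tot <- 0
  for (t in seq_along(u)) {
    Lu <- applyLFourier(u[[t]], mult)
    Lw <- applyLFourier(w[[t]], mult)
    tot <- tot + dt * vol * sum(mapply(
      function(a, b) sum(a * b), Lu@components, Lw@components))
  }
  tot
}

#' Register two images by greedy LDDMM
#'
#' Gradient descent from v = 0 with the per-timestep update
#' `v_t <- v_t - eps * g_t`, eps chosen each iteration by backtracking
#' line search (halved until the total energy does not increase, restored
#' afterwards). Stops when the relative total-energy change stays below
#' `tol` for `tolWindow` iterations, or at `maxIter`.
#'
#' @param I0 atlas [ScalarImage-class] (moving image).
#' @param I1 target [ScalarImage-class] on the same grid; intensities
#'   should be comparable (see [histogramMatch()]).
#' @param params an [LDDMMParams-class].
#' @return a [RegistrationResult-class]; its energy trace is
#'   non-increasing and `jacobianDeterminant(inverseMap(result))` is
#'   strictly positive for converged runs at default settings
#' @export
registerLDDMM <- function(I0, I1, params = LDDMMParams()) {
  grid <- I0@grid
  stopIfGridMismatch(grid, I1@grid, "atlas and target")
  mult <- buildMultipliers(grid, params@kernel)
  T <- params@nTimeSteps
  v <- zeroVelocity(grid, T)
  flow <- integrateFlow(v)
  e <- computeEnergy(flow, v, I0, I1, params, mult)
  if (!all(is.finite(e)))
    stop("non-finite energy at initialization", call. = FALSE)
  trace <- data.frame(iter = 0L, total = e["total"], reg = e["reg"],
                      mismatch = e["mismatch"], stepSize = NA_real_,
                      stage = 1L, row.names = NULL)
  converged <- FALSE
  smallCount <- 0L
  iter <- 0L
  while (iter < params@maxIter) {
    iter <- iter + 1L
    g <- computeGradient(flow, v, I0, I1, params, mult)
    gmax <- max(vapply(g, function(f)
      max(vapply(f@components, function(c) max(abs(c)), numeric(1))),
      numeric(1)))
    if (gmax < 1e-14) { converged <- TRUE; iter <- iter - 1L; break }
    eps <- params@epsilon0
    accepted <- FALSE
    for (try in seq_len(if (params@lineSearch) 30L else 1L)) {
      vNew <- lapply(seq_len(T), function(t) {
        VectorField(lapply(seq_len(gridDim(grid)), function(c) {
          v[[t]]@components[[c]] - eps * g[[t]]@components[[c]]
        }), grid)
      })
      flowNew <- integrateFlow(vNew)
      eNew <- computeEnergy(flowNew, vNew, I0, I1, params, mult)
      if (!all(is.finite(eNew)))
        stop("non-finite energy at iteration ", iter, call. = FALSE)
      # accept only steps that keep the energy non-increasing AND the
      # backward map diffeomorphic (the solver's FlowState contract);
      # with T = 1 the map has no compositional protection, so the
      # Jacobian guard is what keeps small-deformation runs invertible
      if (!params@lineSearch ||
          (eNew["total"] <= e["total"] * (1 + 1e-12) &&
           min(jacobianDeterminant(flowNew$phiInv)@values) > 0)) {
        accepted <- TRUE
        break
      }
      eps <- eps / 2
    }
    if (!accepted) { converged <- TRUE; iter <- iter - 1L; break }
    relChange <- (e["total"] - eNew["total"]) /
      max(abs(e["total"]), .Machine$double.eps)
    v <- vNew; flow <- flowNew; e <- eNew
    trace <- rbind(trace, data.frame(
      iter = iter, total = e["total"], reg = e["reg"],
      mismatch = e["mismatch"], stepSize = eps, stage = 1L,
      row.names = NULL))
    if (abs(relChange) < params@tol) {
      smallCount <- smallCount + 1L
      if (smallCount >= params@tolWindow) { converged <- TRUE; break }
    } else smallCount <- 0L
  }
  new("RegistrationResult", phi = flow$phi, phiInv = flow$phiInv,
      velocity = v, energyTrace = trace, converged = converged,
      iterations = iter, params = params, metricRetained = TRUE)
}

#' Cascaded LDDMM over a decreasing sequence of alpha values
#'
#' Stage i registers the running deformed atlas
#' `I0 . phi_1^-1 . ... . phi_{i-1}^-1` to the target at `alphas[i]`
#' (gamma stays fixed); the final backward map is the composition
#' `phi^-1 = phi_1^-1 . phi_2^-1 . ... . phi_n^-1`. The composed map is
#' still diffeomorphic but is no longer the endpoint of a single
#' geodesic flow, so the metric property is flagged as not retained (for
#' more than one stage).
#'
#' @param I0,I1 atlas and target [ScalarImage-class] objects.
#' @param alphas strictly decreasing vector, e.g. `c(0.01, 0.005, 0.002)`.
#' @param params an [LDDMMParams-class]; its alpha is overridden per
#'   stage.
#' @return a [RegistrationResult-class] with a `stage` column in its
#'   energy trace
#' @export
cascadeRegister <- function(I0, I1, alphas = c(0.01, 0.005, 0.002),
                            params = LDDMMParams()) {
  alphas <- as.numeric(alphas)
  if (length(alphas) < 1L || any(diff(alphas) >= 0))
    stop("alphas must be strictly decreasing", call. = FALSE)
  grid <- I0@grid
  totalInv <- identityMap(grid)
  totalPhi <- identityMap(grid)
  traces <- list()
  vel <- list()
  conv <- TRUE
  iters <- 0L
  res <- NULL
  for (i in seq_along(alphas)) {
    p <- params
    p@kernel <- KernelParams(alphas[i], params@kernel@gamma)
    moving <- if (i == 1L) I0 else warpImage(I0, totalInv)
    res <- registerLDDMM(moving, I1, p)
    totalInv <- composeMaps(totalInv, res@phiInv)
    totalPhi <- composeMaps(res@phi, totalPhi)
    tr <- res@energyTrace
    tr$stage <- i
    traces[[i]] <- tr
    vel <- c(vel, res@velocity)
    conv <- conv && res@converged
    iters <- iters + res@iterations
  }
  new("RegistrationResult", phi = totalPhi, phiInv = totalInv,
      velocity = vel, energyTrace = do.call(rbind, traces),
      converged = conv, iterations = iters, params = res@params,
      metricRetained = length(alphas) == 1L)
}
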