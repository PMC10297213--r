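# Numerical solution of the mass-conserved reaction-diffusion systems:
# forward-Euler five-point stencil on arbitrary masked 2D domains with
# no-flux (mirror ghost) boundaries and mass-conserving pairwise noise, and a
# stiff-capable method-of-lines integrator in 1D.

#' Masked five-point Laplacian with no-flux boundary
#'
#' Applies the discrete five-point Laplace stencil on the mask; for each
#' 4-neighbor outside the mask the flux across that face is zero (the ghost
#' value mirrors the center). Entries outside the mask are \code{NA}.
#'
#' @param field a \linkS4class{GridField} or numeric matrix.
#' @param mask required when \code{field} is a bare matrix.
#' @param dx grid spacing (a.u.).
#' @return Same type as \code{field}.
#' @examples
#' m <- discMask(16, 16, 5)
#' f <- gridField(matrix(1, 16, 16), m)
#' range(fieldValues(maskedLaplacian(f))[maskMatrix(m)])  # constant -> 0
#' @export
maskedLaplacian <- function(field, mask = NULL, dx = 0.02) {
  if (is(field, "GridField")) {
    v <- cpp_masked_laplacian(field@values,
                              matrix(as.integer(field@mask@mask),
                                     nrow(field@values)), dx)
    return(gridField(v, field@mask, component = field@component,
                     nonnegative = FALSE))
  }
  if (is.null(mask)) stop("mask required when field is a matrix")
  m <- if (is(mask, "CellMask")) mask@mask else (mask != 0)
  cpp_masked_laplacian(field, matrix(as.integer(m), nrow(field)), dx)
}

# assemble the list of initial 2D field matrices for a model on a mask
initFields2D <- function(model, mask) {
  cm <- if (is(mask, "CellMask")) mask else cellMask(mask)
  m <- cm@mask
  fields <- lapply(model@components, function(cc) {
    v <- matrix(0, nrow(m), ncol(m))
    v[m] <- model@init[[cc]]
    v
  })
  names(fields) <- model@components
  st <- model@stimulus
  if (length(st)) {
    # point stimulus on the domain edge at the configured angle
    edge <- which(cpp_edge_pixels(matrix(as.integer(m), nrow(m))) == 1L,
                  arr.ind = TRUE)
    ctr <- c(mean(edge[, 1]), mean(edge[, 2]))
    ang <- atan2(edge[, 1] - ctr[1], edge[, 2] - ctr[2])
    px <- edge[which.min(abs(ang - st$angle)), , drop = TRUE]
    fields[[st$active]][px[1], px[2]] <- st$value
    fields[[st$inactive]][px[1], px[2]] <- 0
  }
  fields
}

#' One or more explicit RD steps on a masked 2D domain
#'
#' Forward-Euler update of reaction + diffusion + noise. Per conserved
#' active/inactive pair one noise draw is added to the active form and
#' subtracted from the inactive form; a positivity guard skips the draw for a
#' pixel/pair when it would push either form negative, so the per-pair total
#' mass over the mask is unchanged to floating tolerance.
#'
#' @param fields named list of numeric matrices (one per model component) or
#'   of \linkS4class{GridField}s, in the model's component order.
#' @param mask \linkS4class{CellMask} or binary matrix.
#' @param model a \linkS4class{ModelSpec}.
#' @param cfg a \linkS4class{SolverConfig}; \code{cfg@seed} drives the noise.
#' @param nsteps number of forward-Euler steps.
#' @return Named list of numeric matrices after \code{nsteps} steps.
#' @export
rdStep2D <- function(fields, mask, model, cfg = solverConfig(), nsteps = 1L) {
  m <- if (is(mask, "CellMask")) mask@mask else (mask != 0)
  mats <- lapply(fields, function(f) if (is(f, "GridField")) f@values else f)
  stopifnot(identical(names(mats), model@components))
  for (f in mats) {
    if (any(f[m] < 0)) stop("negative concentration in input state")
  }
  checkStability(cfg, model@diffusion, dim(m))
  cpp_rd_steps(mats, matrix(as.integer(m), nrow(m)), model@pairs,
               unname(model@diffusion), cfg@dt, cfg@dx, cfg@noiseAmp,
               if (cfg@noiseScaling == "sqrt_dt") 1L else 0L,
               as.integer(nsteps), as.double(cfg@seed))
}

#' Run a model on a static masked 2D domain
#'
#' Convenience wrapper: repeated \code{\link{rdStep2D}} blocks on a fixed
#' mask, saving one frame per \code{cfg@saveEvery} iterations.
#'
#' @inheritParams rdStep2D
#' @param nFrames number of saved frames.
#' @return List with \code{fields} (list per component of nrow x ncol x
#'   nFrames arrays) and \code{times} (a.u.).
#' @export
runRD2D <- function(model, mask, cfg = solverConfig(), nFrames = 10L) {
  m <- if (is(mask, "CellMask")) mask@mask else (mask != 0)
  fields <- initFields2D(model, m)
  out <- lapply(fields, function(f) array(NA_real_, c(dim(f), nFrames)))
  seed <- cfg@seed
  for (fr in seq_len(nFrames)) {
    cfg@seed <- seed + fr - 1L  # distinct noise stream per block
    fields <- rdStep2D(fields, m, model, cfg, nsteps = cfg@saveEvery)
    for (k in seq_along(fields)) out[[k]][, , fr] <- fields[[k]]
  }
  list(fields = out, times = seq_len(nFrames) * cfg@saveEvery * cfg@dt)
}

#' Method-of-lines solution of a model in 1D
#'
#' Integrates the model on a 1D domain with no-flux ends using a
#' stiff-capable solver (\code{deSolve::ode.1D}, lsoda). The activation
#' threshold is spatially uniform in 1D and selected by \code{K}.
#'
#' @param model a \linkS4class{ModelSpec}.
#' @param init named numeric (homogeneous per component) or named list of
#'   per-node profiles; defaults to the model's initial conditions.
#' @param domainLength domain size (a.u.; default 4).
#' @param tEnd final time (a.u.).
#' @param nOut number of output times (equally spaced, excluding 0).
#' @param nodes spatial nodes (default 400, i.e. dx = 0.01 on 4 a.u.).
#' @param K \code{"basal"}, \code{"edge"}, or a named numeric of per-pair
#'   threshold overrides (e.g. \code{c(G = 1.4)}).
#' @param perturb amplitude of the half-normal initial perturbation added to
#'   active forms and subtracted from inactive forms (0 disables).
#' @param seed seed for the initial perturbation.
#' @param rtol,atol integrator tolerances.
#' @return List with \code{x} (node centers), \code{times}, and
#'   \code{profiles}: nodes x components x times array.
#' @examples
#' mod <- buildModel("mcrd_single", overrides = list(K1basal = 2.1))
#' sol <- solveRD1D(mod, tEnd = 10, nOut = 2, nodes = 50, perturb = 0)
#' range(sol$profiles[, "Ga", 2] + sol$profiles[, "Gi", 2])  # total = 1
#' @export
solveRD1D <- function(model, init = NULL, domainLength = 4, tEnd = 100,
                      nOut = 50L, nodes = 400L, K = "basal", perturb = 1e-6,
                      seed = 1L, rtol = 1e-6, atol = 1e-9) {
  if (domainLength <= 0) stop("domainLength must be positive")
  ncomp <- length(model@components)
  dx <- domainLength / nodes
  x <- (seq_len(nodes) - 0.5) * dx

  Y0 <- matrix(0, nodes, ncomp, dimnames = list(NULL, model@components))
  if (is.null(init)) init <- model@init
  if (is.list(init)) {
    for (cc in names(init)) Y0[, cc] <- init[[cc]]
  } else {
    for (cc in names(init)) Y0[, cc] <- init[[cc]]
  }
  if (any(Y0 < 0)) stop("initial profiles must be nonnegative")
  if (perturb > 0) {
    set.seed(seed)
    for (p in model@pairs) {
      xi <- perturb * abs(rnorm(nodes))
      Y0[, p$a] <- Y0[, p$a] + xi
      Y0[, p$i] <- pmax(Y0[, p$i] - xi, 0)
    }
  }

  Kl <- list()
  if (is.character(K)) {
    for (p in model@pairs)
      Kl[[p$pair]] <- if (K == "edge") p$Kedge else p$Kbasal
  } else {
    for (p in model@pairs)
      Kl[[p$pair]] <- if (p$pair %in% names(K)) K[[p$pair]] else p$Kbasal
  }

  D <- unname(model@diffusion)
  inv_dx2 <- 1 / dx^2
  rhs <- function(t, y, parms) {
    Y <- matrix(y, nodes, ncomp)
    dY <- reaction_rates(model, Y, Kl)
    for (k in seq_len(ncomp)) {
      v <- Y[, k]
      lap <- (c(v[1], v[-nodes]) + c(v[-1], v[nodes]) - 2 * v) * inv_dx2
      dY[, k] <- dY[, k] + D[k] * lap
    }
    list(as.vector(dY))
  }

  times <- seq(0, tEnd, length.out = nOut + 1L)
  sol <- deSolve::ode.1D(y = as.vector(Y0), times = times, func = rhs,
                         parms = NULL, nspec = ncomp, dimens = nodes,
                         method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("1D integrator failed; last valid time: ", max(sol[, 1]))
  prof <- array(NA_real_, c(nodes, ncomp, length(times)),
                dimnames = list(NULL, model@components, NULL))
  for (ti in seq_along(times))
    prof[, , ti] <- matrix(sol[ti, -1], nodes, ncomp)
  list(x = x, times = times, profiles = prof)
}
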