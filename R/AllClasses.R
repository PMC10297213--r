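# S4 containers for the simulation and analysis layers.

# ---------------------------------------------------------------------------
# CellMask
# ---------------------------------------------------------------------------

#' CellMask: the binary simulation/analysis domain
#'
#' A binary lattice whose foreground is 4-connected, whose background is
#' 4-connected (no holes), with no corner-only (diagonal) contacts in either
#' set, and which keeps a one-pixel margin to the frame border.
#'
#' @slot mask logical matrix; \code{TRUE} = inside the cell.
#' @slot V0 numeric; reference pixel count used by the volume factor
#'   (defaults to the initial foreground size).
#' @export
setClass("CellMask", representation(mask = "matrix", V0 = "numeric"))

# 4-connected component count by label propagation (vectorized; O(diameter)
# sweeps). Used for validity only -- tests carry their own flood-fill oracle.
label_components4 <- function(m) {
  if (!any(m)) return(0L)
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(seq_len(nr * nc), nr, nc)
  lab[!m] <- NA_real_
  repeat {
    up    <- rbind(lab[-1, , drop = FALSE], rep(NA, nc))
    down  <- rbind(rep(NA, nc), lab[-nr, , drop = FALSE])
    left  <- cbind(lab[, -1, drop = FALSE], rep(NA, nr))
    right <- cbind(rep(NA, nr), lab[, -nc, drop = FALSE])
    new <- pmin(lab, up, down, left, right, na.rm = TRUE)
    new[!m] <- NA_real_
    if (identical(new, lab)) break
    lab <- new
  }
  length(unique(lab[m]))
}

has_corner_touch <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 2L || nc < 2L) return(FALSE)
  a <- m[-nr, -nc]; b <- m[-nr, -1]; c_ <- m[-1, -nc]; d <- m[-1, -1]
  any(a & d & !b & !c_) || any(b & c_ & !a & !d)
}

validCellMask <- function(object) {
  m <- object@mask
  msgs <- character()
  if (!is.matrix(m) || !is.logical(m)) msgs <- c(msgs, "mask must be a logical matrix")
  else {
    if (!any(m)) msgs <- c(msgs, "mask is empty")
    else {
      if (any(m[1, ]) || any(m[nrow(m), ]) || any(m[, 1]) || any(m[, ncol(m)]))
        msgs <- c(msgs, "mask must keep a one-pixel margin to the frame border")
      if (label_components4(m) != 1L)
        msgs <- c(msgs, "mask foreground must be 4-connected")
      if (label_components4(!m) != 1L)
        msgs <- c(msgs, "mask background must be 4-connected (no holes)")
      if (has_corner_touch(m))
        msgs <- c(msgs, "mask contains a corner-only (diagonal) contact")
    }
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("CellMask", validCellMask)

#' Construct a CellMask
#'
#' @param mask logical or 0/1 matrix.
#' @param V0 reference pixel count (defaults to \code{sum(mask)}).
#' @return A \linkS4class{CellMask}.
#' @examples
#' m <- discMask(32, 32, radius = 10)
#' volume(m)
#' @export
cellMask <- function(mask, V0 = sum(mask != 0)) {
  m <- mask != 0
  storage.mode(m) <- "logical"
  new("CellMask", mask = m, V0 = as.numeric(V0))
}

#' Circular cell mask
#'
#' @param nrow,ncol frame size in pixels.
#' @param radius disc radius in pixels.
#' @param center optional c(row, col) center; defaults to the frame center.
#' @return A \linkS4class{CellMask} containing the disc.
#' @export
discMask <- function(nrow, ncol = nrow, radius = floor(min(nrow, ncol) / 2) - 2,
                     center = NULL) {
  if (is.null(center)) center <- c((nrow + 1) / 2, (ncol + 1) / 2)
  r <- matrix(seq_len(nrow), nrow, ncol)
  c_ <- matrix(rep(seq_len(ncol), each = nrow), nrow, ncol)
  m <- (r - center[1])^2 + (c_ - center[2])^2 <= radius^2
  cellMask(m)
}

# ---------------------------------------------------------------------------
# GridField
# ---------------------------------------------------------------------------

#' GridField: per-pixel concentration of one model component
#'
#' @slot values numeric matrix (a.u. concentration); entries outside the mask
#'   are ignored.
#' @slot mask the \linkS4class{CellMask} domain.
#' @slot component component identifier (e.g. \code{"Ga"}, \code{"Ia"}).
#' @slot nonnegative logical; concentration fields must be nonnegative inside
#'   the mask, rate-of-change fields may carry either sign.
#' @export
setClass("GridField",
         representation(values = "matrix", mask = "CellMask",
                        component = "character", nonnegative = "logical"),
         prototype(nonnegative = TRUE))

setValidity("GridField", function(object) {
  msgs <- character()
  if (!identical(dim(object@values), dim(object@mask@mask)))
    msgs <- c(msgs, "field and mask dimensions differ")
  else if (object@nonnegative &&
           any(object@values[object@mask@mask] < 0, na.rm = TRUE))
    msgs <- c(msgs, "negative concentration inside the mask")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GridField
#'
#' @param values numeric matrix.
#' @param mask a \linkS4class{CellMask} (or matrix coercible to one).
#' @param component component id.
#' @param nonnegative enforce nonnegativity inside the mask.
#' @return A \linkS4class{GridField}.
#' @export
gridField <- function(values, mask, component = "X", nonnegative = TRUE) {
  if (!is(mask, "CellMask")) mask <- cellMask(mask)
  new("GridField", values = values, mask = mask, component = component,
      nonnegative = nonnegative)
}

# ---------------------------------------------------------------------------
# SolverConfig
# ---------------------------------------------------------------------------

#' SolverConfig: explicit-scheme solver settings
#'
#' @slot dt forward-Euler time step (a.u.).
#' @slot dx grid spacing (a.u.).
#' @slot noiseAmp amplitude of the mass-conserved pairwise noise.
#' @slot noiseScaling \code{"dt"} (Euler increment dt*alpha*xi, the default) or
#'   \code{"sqrt_dt"}.
#' @slot rdItersPerEvent RD iterations between morphodynamic events.
#' @slot saveEvery RD iterations per saved frame (1000 = 1 a.u.).
#' @slot seed integer seed driving every random draw of a simulation.
#' @export
setClass("SolverConfig",
         representation(dt = "numeric", dx = "numeric", noiseAmp = "numeric",
                        noiseScaling = "character", rdItersPerEvent = "integer",
                        saveEvery = "integer", seed = "integer"))

setValidity("SolverConfig", function(object) {
  msgs <- character()
  if (object@dt <= 0 || object@dx <= 0) msgs <- c(msgs, "dt and dx must be positive")
  if (!object@noiseScaling %in% c("dt", "sqrt_dt"))
    msgs <- c(msgs, "noiseScaling must be 'dt' or 'sqrt_dt'")
  if (object@rdItersPerEvent < 1L) msgs <- c(msgs, "rdItersPerEvent must be >= 1")
  if (object@saveEvery < 1L) msgs <- c(msgs, "saveEvery must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SolverConfig
#'
#' Defaults: dx = 0.02 a.u. per pixel, noise amplitude 5, one
#' protrusion-retraction cycle per 0.05 a.u. and one saved frame per 1 a.u.
#' of simulation time. The default step dt = 5e-4 is the largest clean value
#' satisfying the 2D five-point von Neumann bound dt * D_max / dx^2 < 1/4
#' for the fastest diffusing component (D = 0.13);
#' \code{rdItersPerEvent = 100} and \code{saveEvery = 2000} keep the event
#' and frame cadence at 0.05 and 1 a.u.
#'
#' The reference noise condition is amplitude 5 with Euler increments at a
#' step of 0.001; \code{noiseAmp = NULL} (the default) rescales the amplitude
#' by \code{sqrt(0.001 / dt)} so that the variance rate of the injected noise
#' is independent of the chosen step (5 * sqrt(2) ~ 7.07 at the default dt).
#' An explicit \code{noiseAmp} is used as given.
#'
#' @param dt,dx,noiseAmp,noiseScaling,rdItersPerEvent,saveEvery,seed see slots.
#' @return A \linkS4class{SolverConfig}.
#' @export
solverConfig <- function(dt = 5e-4, dx = 0.02, noiseAmp = NULL,
                         noiseScaling = c("dt", "sqrt_dt"),
                         rdItersPerEvent = 100L, saveEvery = 2000L, seed = 1L) {
  if (is.null(noiseAmp)) noiseAmp <- 5 * sqrt(0.001 / dt)
  new("SolverConfig", dt = dt, dx = dx, noiseAmp = noiseAmp,
      noiseScaling = match.arg(noiseScaling),
      rdItersPerEvent = as.integer(rdItersPerEvent),
      saveEvery = as.integer(saveEvery), seed = as.integer(seed))
}

# check the explicit-scheme von Neumann bound against a model's fastest
# diffusion: dt * D / dx^2 < 1/4 on 2D domains, < 1/2 on 1-pixel strips
checkStability <- function(cfg, D, dims = c(2L, 2L)) {
  bound <- if (min(dims) > 1L) 0.25 else 0.5
  co <- cfg@dt * max(D) / cfg@dx^2
  if (co >= bound)
    stop("explicit scheme unstable: dt * D_max / dx^2 = ", signif(co, 3),
         " >= ", bound, "; reduce dt or increase dx")
  invisible(co)
}

# ---------------------------------------------------------------------------
# MorphoParams
# ---------------------------------------------------------------------------

#' MorphoParams: protrusion/retraction probability parameters
#'
#' @slot g curvature sensitivity of the geometry factor.
#' @slot k smoothing exponent of the geometry factor.
#' @slot alphaV,betaV,gammaV volume-factor sharpness and deviations.
#' @slot alphaA,betaA,gammaA,Aact actin-factor sharpness, deviations and
#'   activation threshold.
#' @slot actinMode \code{"concentration"} (actin factor reads the active-form
#'   concentration) or \code{"rate"} (its temporal derivative over one
#'   protrusion-retraction cycle).
#' @slot minPixels retraction never shrinks the mask below this size.
#' @slot V0 reference volume; \code{NA} = initial mask size.
#' @export
setClass("MorphoParams",
         representation(g = "numeric", k = "numeric", alphaV = "numeric",
                        betaV = "numeric", gammaV = "numeric",
                        alphaA = "numeric", betaA = "numeric",
                        gammaA = "numeric", Aact = "numeric",
                        actinMode = "character", minPixels = "integer",
                        V0 = "numeric"))

setValidity("MorphoParams", function(object) {
  msgs <- character()
  dev <- c(object@betaV, object@gammaV, object@betaA, object@gammaA)
  if (any(dev < 0) || any(dev > 0.5))
    msgs <- c(msgs, "betaV, gammaV, betaA, gammaA must lie in [0, 0.5]")
  if (!object@actinMode %in% c("concentration", "rate"))
    msgs <- c(msgs, "actinMode must be 'concentration' or 'rate'")
  if (length(msgs)) msgs else TRUE
})

#' Construct MorphoParams
#'
#' Geometry and volume defaults (g = 2, k = 3, alphaV = 1e-3,
#' betaV = gammaV = 0.5) are shared by all models; actin-factor parameters
#' differ per model and regulation mode -- see \code{\link{actinPreset}}.
#'
#' @param g,k,alphaV,betaV,gammaV,alphaA,betaA,gammaA,Aact,actinMode,minPixels,V0
#'   see slots.
#' @return A \linkS4class{MorphoParams}.
#' @export
morphoParams <- function(g = 2, k = 3, alphaV = 1e-3, betaV = 0.5,
                         gammaV = 0.5, alphaA = 50, betaA = 0, gammaA = 0.2,
                         Aact = 0.1, actinMode = c("rate", "concentration"),
                         minPixels = 20L, V0 = NA_real_) {
  new("MorphoParams", g = g, k = k, alphaV = alphaV, betaV = betaV,
      gammaV = gammaV, alphaA = alphaA, betaA = betaA, gammaA = gammaA,
      Aact = Aact, actinMode = match.arg(actinMode),
      minPixels = as.integer(minPixels), V0 = V0)
}

# ---------------------------------------------------------------------------
# ModelSpec
# ---------------------------------------------------------------------------

#' ModelSpec: a named reaction system
#'
#' Holds the components, conserved active/inactive pairs with their kinetic
#' parameters, diffusion coefficients, total concentrations, initial
#' conditions, and the edge/basal activation-threshold values of one of the
#' six registered models.
#'
#' @slot name model name.
#' @slot components component ids, active form first within each pair.
#' @slot pairs list of per-pair parameter lists consumed by the solvers.
#' @slot params the flat named kinetic parameter list (paper-style names).
#' @slot diffusion named diffusion coefficient per component.
#' @slot totals named total concentration per pair.
#' @slot init named homogeneous initial condition per component.
#' @slot actinComponent which active form drives the actin factor.
#' @slot stimulus optional stimulus description for excitable variants.
#' @export
setClass("ModelSpec",
         representation(name = "character", components = "character",
                        pairs = "list", params = "list",
                        diffusion = "numeric", totals = "numeric",
                        init = "numeric", actinComponent = "character",
                        stimulus = "list"))

setValidity("ModelSpec", function(object) {
  msgs <- character()
  for (p in object@pairs) {
    rates <- c(p$kon, p$koff, p$gamma, p$alpha, p$mu, p$beta)
    if (any(rates < 0)) msgs <- c(msgs, "kinetic rates must be nonnegative")
  }
  if (any(object@totals <= 0)) msgs <- c(msgs, "total concentrations must be positive")
  if (!object@actinComponent %in% object@components)
    msgs <- c(msgs, "actinComponent not among components")
  if (length(msgs)) msgs else TRUE
})

# ---------------------------------------------------------------------------
# Pipeline containers
# ---------------------------------------------------------------------------

#' ContourSet: outer, inner and mid contour of a time window
#'
#' @slot outer,inner,mid n x 2 matrices of (x, y) pixel coordinates, resampled
#'   at 1-px arc-length spacing; the outer contour bounds the union of the
#'   window's masks, the inner contour their intersection.
#' @slot frames the frame indices of the window.
#' @export
setClass("ContourSet",
         representation(outer = "matrix", inner = "matrix", mid = "matrix",
                        frames = "integer"))

#' TrajectoryBundle: piecewise-linear edge trajectories
#'
#' @slot x,y trajectory x frame matrices of intersection coordinates (px); NA
#'   where a trajectory is not alive.
#' @slot velocity signed edge velocity (px/frame, protrusion positive);
#'   defined from each trajectory's second frame onward.
#' @slot signal near-edge biosensor signal sampled along the trajectories.
#' @export
setClass("TrajectoryBundle",
         representation(x = "matrix", y = "matrix", velocity = "matrix",
                        signal = "matrix"))

#' Kymograph: trajectories x frames matrix of velocity or signal
#'
#' @slot data trajectories x frames matrix.
#' @slot kind \code{"velocity"} or \code{"signal"}.
#' @slot peaks data.frame with columns \code{trajectory}, \code{frame} of
#'   annotated velocity peaks (possibly empty).
#' @export
setClass("Kymograph",
         representation(data = "matrix", kind = "character",
                        peaks = "data.frame"))

setValidity("Kymograph", function(object) {
  if (!object@kind %in% c("velocity", "signal"))
    "kind must be 'velocity' or 'signal'" else TRUE
})

#' PeakSummary: velocity-peak-aligned traces
#'
#' Mean traces over a window of -20..+20 frames around detected velocity
#' peaks (41 samples each) with 97.5\% confidence half-widths.
#'
#' @slot velocity,signal,signalDeriv,coordinate mean aligned traces; the
#'   coordinate trace is the running integral (cumulative sum) of the velocity
#'   trace.
#' @slot ciVelocity,ciSignal confidence half-widths.
#' @slot nPeaks number of peaks averaged.
#' @slot lag frame offset of the signal-trace maximum relative to the velocity
#'   peak (positive = signal peaks after velocity).
#' @export
setClass("PeakSummary",
         representation(velocity = "numeric", signal = "numeric",
                        signalDeriv = "numeric", coordinate = "numeric",
                        ciVelocity = "numeric", ciSignal = "numeric",
                        nPeaks = "integer", lag = "numeric"))

setValidity("PeakSummary", function(object) {
  if (object@nPeaks > 0L && length(object@velocity) != 41L)
    "aligned traces must have exactly 41 samples (-20..+20 frames)" else TRUE
})
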