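# Stochastic protrusion/retraction engine on the binary cell mask, coupled to
# the reaction-diffusion state. Event probabilities multiply three factors:
# local curvature (geometry), cell-size homeostasis (volume) and local
# actin-polymerization signaling (actin).

as_int_mask <- function(mask) {
  m <- if (is(mask, "CellMask")) mask@mask else (mask != 0)
  matrix(as.integer(m), nrow(m))
}

#' Geometry factor of a protrusion/retraction candidate
#'
#' Distance-weighted fraction of like pixels in the 8-neighborhood, raised to
#' the smoothing power:
#' \deqn{w = \left(\frac{\sum_{8nb} m' d^{-g}}{\sum_{8nb} d^{-g}}\right)^k}
#' with \eqn{m'} the mask for protrusion and the inverted mask for
#' retraction, and \eqn{d \in \{1, \sqrt 2\}} the neighbor distance. Convex
#' (high-curvature) regions are less likely to protrude and more likely to
#' retract; concave regions the opposite.
#'
#' @param mask \linkS4class{CellMask} or binary matrix.
#' @param pixel c(row, col) of the candidate: a background pixel 4-adjacent
#'   to the mask for protrusion, a foreground outline pixel for retraction.
#' @param mode \code{"protrude"} or \code{"retract"}.
#' @param g curvature sensitivity (weight decay with distance).
#' @param k smoothing exponent.
#' @return Probability factor in [0, 1].
#' @export
geometryFactor <- function(mask, pixel, mode = c("protrude", "retract"),
                           g = 2, k = 3) {
  mode <- match.arg(mode)
  m <- as_int_mask(mask)
  r <- pixel[1]; c_ <- pixel[2]
  inm <- m[r, c_] == 1L
  nb4 <- c(if (r > 1) m[r - 1, c_], if (r < nrow(m)) m[r + 1, c_],
           if (c_ > 1) m[r, c_ - 1], if (c_ < ncol(m)) m[r, c_ + 1])
  ok <- if (mode == "protrude") !inm && any(nb4 == 1L) else inm && any(nb4 == 0L)
  if (!ok) stop("pixel is not a valid ", mode, " candidate (not on the outline)")
  cpp_geometry_factor(m, r, c_, mode == "protrude", g, k)
}

#' Volume factor
#'
#' Sigmoidal homeostasis of cell size: growing past the reference volume V0
#' suppresses protrusion (toward 1/2 - gammaV) and promotes retraction;
#' shrinking below it does the opposite (toward 1/2 + betaV).
#'
#' @param V current pixel count.
#' @param V0 reference pixel count.
#' @param alphaV sharpness of the sigmoid.
#' @param betaV,gammaV probability deviations from 1/2 for shrunk/grown cells.
#' @param mode \code{"protrude"} or \code{"retract"}.
#' @return Probability factor in [0, 1].
#' @export
volumeFactor <- function(V, V0, alphaV = 1e-3, betaV = 0.5, gammaV = 0.5,
                         mode = c("protrude", "retract")) {
  mode <- match.arg(mode)
  s <- 1 - 1 / (1 + exp(alphaV * (V - V0)))
  if (mode == "protrude") 0.5 + betaV - (betaV + gammaV) * s
  else 0.5 - betaV + (betaV + gammaV) * s
}

#' Actin factor
#'
#' Sigmoidal response to the local actin-polymerization drive A (active-form
#' concentration or its rate of change): weak drive leaves protrusion and
#' retraction balanced at 1/2 (for betaA = 0), drive above the threshold Aact
#' biases toward protrusion (1/2 + gammaA) and away from retraction.
#'
#' @param A local drive value.
#' @param alphaA sharpness.
#' @param betaA,gammaA probability deviations below/above threshold.
#' @param Aact activation threshold.
#' @param mode \code{"protrude"} or \code{"retract"}.
#' @return Probability factor in [0, 1].
#' @export
actinFactor <- function(A, alphaA = 50, betaA = 0, gammaA = 0.2, Aact = 0.1,
                        mode = c("protrude", "retract")) {
  mode <- match.arg(mode)
  s <- 1 - 1 / (1 + exp(alphaA * (A - Aact)))
  if (mode == "protrude") 0.5 - betaA + (betaA + gammaA) * s
  else 0.5 + betaA - (betaA + gammaA) * s
}

#' Extrapolate a field value to a background candidate pixel
#'
#' Mean of the field over the in-mask pixels of the candidate's
#' 8-neighborhood (used to evaluate the actin factor at protrusion
#' candidates, which lie outside the mask).
#'
#' @param field \linkS4class{GridField} or numeric matrix.
#' @param mask \linkS4class{CellMask} or binary matrix.
#' @param pixel c(row, col) of a background pixel 8-adjacent to the mask.
#' @return The extrapolated value.
#' @export
extrapolateActin <- function(field, mask, pixel) {
  v <- if (is(field, "GridField")) field@values else field
  m <- as_int_mask(mask)
  r <- pixel[1]; c_ <- pixel[2]
  rr <- pmax(1, r - 1):pmin(nrow(m), r + 1)
  cc <- pmax(1, c_ - 1):pmin(ncol(m), c_ + 1)
  w <- m[rr, cc] == 1L
  w[rr == r, cc == c_] <- FALSE
  if (!any(w)) stop("pixel has no in-mask neighbor (not a valid candidate)")
  mean(v[rr, cc][w])
}

#' Actin input field from the state history
#'
#' \code{"concentration"} returns the current active-form field;
#' \code{"rate"} the finite-difference temporal derivative
#' \eqn{(X_a(t) - X_a(t - \Delta)) / \Delta} with \eqn{\Delta} one
#' protrusion-retraction cycle by default.
#'
#' @param history list of named field-matrix lists, oldest first (at least 2
#'   entries for rate mode).
#' @param mode \code{"concentration"} or \code{"rate"}.
#' @param component active-form component id.
#' @param delta time between the last two history entries (a.u.).
#' @return Numeric matrix of the actin drive.
#' @export
actinInput <- function(history, mode = c("concentration", "rate"),
                       component = "Ga", delta = 0.05) {
  mode <- match.arg(mode)
  n <- length(history)
  if (n < 1L) stop("empty state history")
  if (mode == "concentration") return(history[[n]][[component]])
  if (n < 2L) stop("rate mode needs at least two saved sub-states")
  (history[[n]][[component]] - history[[n - 1L]][[component]]) / delta
}

#' Apply one protrusion or retraction event
#'
#' Each candidate is accepted independently with its supplied probability;
#' accepted events are then committed one at a time in random order, with a
#' digital-topology guard that rejects any event that would 4-disconnect the
#' mask or its background, create a hole, or leave a corner-only (diagonal)
#' contact -- so of two conflicting diagonal events only one takes place.
#'
#' @param mask \linkS4class{CellMask} or binary matrix.
#' @param probabilities numeric matrix of per-pixel acceptance probabilities
#'   (evaluated at protrusion/retraction candidates, ignored elsewhere).
#' @param seed seed for the acceptance draws and commit order.
#' @param minPixels retraction floor on the mask size.
#' @return List with the updated \code{mask} (\linkS4class{CellMask}) and
#'   \code{applied}, the linear indices of committed pixels.
#' @export
protrusionStep <- function(mask, probabilities, seed = 1L) {
  res <- cpp_protrusion_step(as_int_mask(mask), probabilities,
                             as.double(seed))
  V0 <- if (is(mask, "CellMask")) mask@V0 else sum(mask != 0)
  list(mask = cellMask(res$mask, V0 = V0), applied = res$applied)
}

#' @rdname protrusionStep
#' @export
retractionStep <- function(mask, probabilities, seed = 1L, minPixels = 20L) {
  res <- cpp_retraction_step(as_int_mask(mask), probabilities,
                             as.double(seed), as.integer(minPixels))
  V0 <- if (is(mask, "CellMask")) mask@V0 else sum(mask != 0)
  list(mask = cellMask(res$mask, V0 = V0), applied = res$applied)
}

#' Redistribute molecular mass across a mask change
#'
#' For added pixels: each new pixel is initialized with the mean of its
#' old-mask 8-neighbors, and the total mass so created is subtracted evenly
#' from all new-mask pixels (skipping pixels that would go negative, with the
#' remainder re-spread so conservation is exact). For removed pixels: their
#' total mass is added evenly across the new mask. Growing the domain thus
#' lowers concentrations but never changes total mass.
#'
#' @param state named list of field matrices.
#' @param oldMask,newMask masks differing by added pixels only or removed
#'   pixels only.
#' @return The updated named list of field matrices.
#' @export
redistributeMass <- function(state, oldMask, newMask) {
  cpp_redistribute(state, as_int_mask(oldMask), as_int_mask(newMask))
}

#' Actin-factor presets per model
#'
#' Sharpness, threshold and protrusion-bias deviation of the actin factor
#' were tuned per reaction system (and, for the single-GTPase ruffling model,
#' per regulation mode):
#' concentration-regulated ruffling (30, 0.7, 0.1), rate-regulated ruffling
#' (50, 0.1, 0.2), Cdc42-induced Rac1 (50, 0.3, 0.2), bidirectional coupling
#' (50, 0.2, 0.35), upstream regulator simultaneous (100, 0.1, 0.1) /
#' delayed (30, 0.5, 0.1), upstream + feedback (30, 0.3, 0.1).
#'
#' @param name model name (see \code{\link{buildModel}}).
#' @param mode actin regulation mode.
#' @param variant for \code{upstream_effector}: which activation preset.
#' @return A \linkS4class{MorphoParams} with the matching actin parameters.
#' @export
actinPreset <- function(name, mode = c("rate", "concentration"),
                        variant = c("simultaneous", "delayed")) {
  name <- match.arg(name, MODEL_NAMES)
  mode <- match.arg(mode)
  variant <- match.arg(variant)
  row <- switch(name,
    mcrd_single = ,
    gtpase_inhibitor = if (mode == "concentration") c(30, 0.7, 0.1)
                       else c(50, 0.1, 0.2),
    cdc42_induces_rac1 = c(50, 0.3, 0.2),
    bidirectional = c(50, 0.2, 0.35),
    upstream_effector = if (variant == "delayed") c(30, 0.5, 0.1)
                        else c(100, 0.1, 0.1),
    upstream_plus_feedback = c(30, 0.3, 0.1))
  morphoParams(alphaA = row[1], Aact = row[2], gammaA = row[3],
               actinMode = mode)
}

#' Simulate a ruffling cell
#'
#' The main coupled loop: one protrusion event, one retraction event (each a
#' Monte-Carlo sweep over outline candidates with probability
#' geometry x volume x actin, committed under the topology guard), mass
#' redistribution, refresh of the edge/basal threshold map, then
#' \code{cfg@rdItersPerEvent} forward-Euler RD iterations; one frame is saved
#' every \code{cfg@saveEvery} RD iterations (default 1000 = 1 a.u.).
#'
#' @param model a \linkS4class{ModelSpec}.
#' @param morpho a \linkS4class{MorphoParams} (see \code{\link{actinPreset}}).
#' @param cfg a \linkS4class{SolverConfig}.
#' @param mask0 initial \linkS4class{CellMask} (circular by default).
#' @param nFrames number of saved frames.
#' @param burnIn frames (a.u.) simulated and discarded before saving starts,
#'   so that analyses see stationary ruffling rather than the ignition
#'   transient of the pattern-forming system.
#' @return List with \code{masks} (nrow x ncol x nFrames binary array),
#'   \code{fields} (named list of nrow x ncol x nFrames arrays),
#'   \code{volume} (pixel count per frame), \code{times} (a.u.), and the
#'   \code{model}, \code{morpho}, \code{cfg} used.
#' @examples
#' \donttest{
#' sim <- simulateCell(buildModel("gtpase_inhibitor"),
#'                     actinPreset("gtpase_inhibitor", "rate"),
#'                     solverConfig(seed = 7), discMask(60, 60, 20),
#'                     nFrames = 5)
#' sim$volume
#' }
#' @export
simulateCell <- function(model, morpho = actinPreset(modelName(model)),
                         cfg = solverConfig(),
                         mask0 = discMask(100, 100, 40), nFrames = 100L,
                         burnIn = 0L) {
  m0 <- as_int_mask(mask0)
  checkStability(cfg, model@diffusion, dim(m0))
  fields <- initFields2D(model, m0 == 1L)
  actin_comp <- match(model@actinComponent, model@components)
  mp <- list(g = morpho@g, k = morpho@k, alphaV = morpho@alphaV,
             betaV = morpho@betaV, gammaV = morpho@gammaV,
             alphaA = morpho@alphaA, betaA = morpho@betaA,
             gammaA = morpho@gammaA, Aact = morpho@Aact,
             actinMode = if (morpho@actinMode == "rate") 1L else 0L,
             actinComp = actin_comp, minPixels = morpho@minPixels,
             V0 = if (is.na(morpho@V0)) -1 else morpho@V0)
  total <- as.integer(nFrames) + as.integer(burnIn)
  res <- cpp_simulate_cell(m0, fields, model@pairs, unname(model@diffusion),
                           mp, cfg@dt, cfg@dx, cfg@noiseAmp,
                           if (cfg@noiseScaling == "sqrt_dt") 1L else 0L,
                           cfg@rdItersPerEvent, cfg@saveEvery,
                           total, as.double(cfg@seed))
  keep <- (as.integer(burnIn) + 1L):total
  list(masks = res$masks[, , keep, drop = FALSE],
       fields = lapply(res$fields, function(a) a[, , keep, drop = FALSE]),
       volume = res$volume[keep],
       times = keep * cfg@saveEvery * cfg@dt,
       model = model, morpho = morpho, cfg = cfg)
}
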