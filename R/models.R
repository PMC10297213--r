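# Registry of the six reaction systems.
#
# Every model is built from conserved active/inactive pairs. A GTPase-type
# pair has the Hill-form net activation rate
#   (kon + (gamma + alpha*S1a^2 + mu*S2a^2) * Xa^2 / (K^2 + beta*Ia^2 + Xa^2)) * Xi
#   - koff * Xa
# while an inhibitor pair has
#   (kon + gamma * Sa^2) * Xi - koff * Xa.
# Cross-coupling sources (S1a, S2a) and the inhibitor concentration Ia are the
# local instantaneous active-form values at the same pixel. The activation
# threshold K takes a smaller value on mask-edge pixels than in the interior
# (K_edge <= K_basal), which is what localizes activity patches at the cell
# boundary.

MODEL_NAMES <- c("mcrd_single", "gtpase_inhibitor", "cdc42_induces_rac1",
                 "bidirectional", "upstream_effector", "upstream_plus_feedback")

# pair constructor; src1/src2/inhib are component indices (0 = none)
rd_pair <- function(label, a, i, kon, koff, gamma, Kedge = 1, Kbasal = 1,
                    alpha = 0, src1 = 0L, mu = 0, src2 = 0L,
                    beta = 0, inhib = 0L, hill = TRUE) {
  list(pair = label, a = as.integer(a), i = as.integer(i), kon = kon,
       koff = koff, gamma = gamma, alpha = alpha, src1 = as.integer(src1),
       mu = mu, src2 = as.integer(src2), beta = beta, inhib = as.integer(inhib),
       Kedge = Kedge, Kbasal = Kbasal, hill = isTRUE(hill))
}

model_defaults <- function(name) {
  switch(name,
    mcrd_single = list(
      k1 = 0.005, gamma1 = 2, K1edge = 1.4, K1basal = 2.1, k2 = 0.1,
      D_Ga = 0.001, D_Gi = 0.13, Gtc = 1),
    gtpase_inhibitor = list(
      k1 = 0.005, gamma1 = 2, K1edge = 1.4, K1basal = 2.1, beta1 = 0.5,
      k2 = 0.1, k3 = 1e-5, gamma3 = 0.2, k4 = 1e-2,
      D_Ga = 0.001, D_Gi = 0.13, D_Ia = 0.003, D_Ii = 0.13,
      Gtc = 1, Itc = 3),
    cdc42_induces_rac1 = list(
      k1 = 0.005, gamma1 = 2, K1edge = 1.4, K1basal = 2.1, beta1 = 0.5,
      k2 = 0.1, k3 = 1e-5, gamma3 = 0.2, k4 = 1e-2,
      k5 = 0.005, gamma5 = 0.3, alpha5 = 0.8, K5edge = 1.4, K5basal = 2.1,
      k6 = 0.1,
      D_Ca = 0.001, D_Ci = 0.13, D_Ia = 0.003, D_Ii = 0.13,
      D_Ra = 0.001, D_Ri = 0.13, Ctc = 1, Itc = 3, Rtc = 1),
    bidirectional = list(
      k1 = 0.005, gamma1 = 1.5, alpha1 = 0.85, K1edge = 1.4, K1basal = 2.1,
      beta1 = 0.5, k2 = 0.1, k3 = 1e-5, gamma3 = 0.2, k4 = 1e-2,
      k5 = 0.07, gamma5 = 1.5, alpha5 = 0.1, K5edge = 0.45, K5basal = 0.5,
      k6 = 1.15,
      D_Ra = 0.001, D_Ri = 0.13, D_Ia = 0.003, D_Ii = 0.13,
      D_Ca = 0.001, D_Ci = 0.13, Rtc = 1, Itc = 3, Ctc = 1),
    upstream_effector = list(
      k1 = 0.005, gamma1 = 2, K1edge = 1.4, K1basal = 2.1, beta1 = 0.5,
      k2 = 0.1, k3 = 1e-5, gamma3 = 0.2, k4 = 1e-2,
      k5 = 0.005, gamma5 = 0.1, alpha5 = 2, K5edge = 1.4, K5basal = 2.1,
      k6 = 0.1, k7 = 0.005, k8 = 0.1,
      # simultaneous-activation variant; the delayed variant overrides these
      gamma7 = 0.1, alpha7 = 2, K7edge = 1.4, K7basal = 2.1,
      D_Pa = 0.001, D_Pi = 0.13, D_Ia = 0.003, D_Ii = 0.13,
      D_Ca = 0.001, D_Ci = 0.13, D_Ra = 0.001, D_Ri = 0.13,
      Ptc = 1, Itc = 3, Ctc = 1, Rtc = 1),
    upstream_plus_feedback = list(
      k1 = 0.005, gamma1 = 2, K1edge = 1.4, K1basal = 2.1, beta1 = 0.5,
      k2 = 0.1, k3 = 1e-5, gamma3 = 0.2, k4 = 1e-2,
      k5 = 0.005, gamma5 = 1, alpha5 = 2, K5edge = 1.4, K5basal = 2.1,
      k6 = 0.1, k7 = 0.005, gamma7 = 0.1, alpha7 = 0.4, mu7 = 0.06,
      K7edge = 1.4, K7basal = 2.1, k8 = 0.1,
      D_Pa = 0.001, D_Pi = 0.13, D_Ia = 0.003, D_Ii = 0.13,
      D_Ca = 0.001, D_Ci = 0.13, D_Ra = 0.001, D_Ri = 0.13,
      Ptc = 1, Itc = 3, Ctc = 1, Rtc = 1),
    stop("unknown model '", name, "'; valid models: ",
         paste(MODEL_NAMES, collapse = ", "))
  )
}

# override set for the delayed-activation variant of the upstream model
upstream_delayed_overrides <- function() {
  list(gamma7 = 0, alpha7 = 15, K7edge = 4, K7basal = 6)
}

#' Build one of the registered reaction systems
#'
#' Assembles a \linkS4class{ModelSpec} with the model's default kinetic
#' parameters, diffusion coefficients, total concentrations and initial
#' conditions. The six models are:
#' \describe{
#'   \item{\code{mcrd_single}}{the two-component mass-conserved core (active +
#'     inactive GTPase with autocatalytic Hill feedback).}
#'   \item{\code{gtpase_inhibitor}}{the core plus a slow inhibitor that raises
#'     the activation threshold (excitable or oscillatory).}
#'   \item{\code{cdc42_induces_rac1}}{Cdc42 + inhibitor driving Rac1 through a
#'     cross-activation gain (delayed Rac1 activation).}
#'   \item{\code{bidirectional}}{Rac1 and Cdc42 bistable motifs coupled in
#'     both directions (polarized ruffling, simultaneous activation).}
#'   \item{\code{upstream_effector}}{both GTPases driven by a common upstream
#'     effector; \code{variant = "delayed"} raises the Rac1 response
#'     threshold.}
#'   \item{\code{upstream_plus_feedback}}{upstream effector plus Cdc42-to-Rac1
#'     feedback of strength \code{mu7}, which can compensate the Rac1 delay.}
#' }
#'
#' @param name model name.
#' @param overrides named list of parameter overrides; only parameters
#'   declared by the model may be touched.
#' @param variant for \code{upstream_effector}: \code{"simultaneous"} or
#'   \code{"delayed"} Rac1/Cdc42 activation preset.
#' @return A \linkS4class{ModelSpec}.
#' @examples
#' mod <- buildModel("gtpase_inhibitor")
#' kineticParams(mod)$gamma1
#' @export
buildModel <- function(name, overrides = list(),
                       variant = c("simultaneous", "delayed")) {
  name <- match.arg(name, MODEL_NAMES)
  variant <- match.arg(variant)
  p <- model_defaults(name)
  if (name == "upstream_effector" && variant == "delayed")
    p <- modifyList(p, upstream_delayed_overrides())
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(p))
    if (length(bad))
      stop("unknown parameter(s) for model '", name, "': ",
           paste(bad, collapse = ", "), "; declared parameters: ",
           paste(names(p), collapse = ", "))
    p <- modifyList(p, overrides)
  }

  spec <- switch(name,
    mcrd_single = list(
      components = c("Ga", "Gi"),
      pairs = list(
        rd_pair("G", 1, 2, p$k1, p$k2, p$gamma1, p$K1edge, p$K1basal)),
      totals = c(G = p$Gtc),
      init = c(Ga = 0, Gi = p$Gtc),
      actin = "Ga", stimulus = list()),
    gtpase_inhibitor = list(
      components = c("Ga", "Gi", "Ia", "Ii"),
      pairs = list(
        rd_pair("G", 1, 2, p$k1, p$k2, p$gamma1, p$K1edge, p$K1basal,
                beta = p$beta1, inhib = 3),
        rd_pair("I", 3, 4, p$k3, p$k4, p$gamma3, src1 = 1, hill = FALSE)),
      totals = c(G = p$Gtc, I = p$Itc),
      init = c(Ga = 0, Gi = p$Gtc, Ia = 0, Ii = p$Itc),
      actin = "Ga", stimulus = list()),
    cdc42_induces_rac1 = list(
      components = c("Ca", "Ci", "Ia", "Ii", "Ra", "Ri"),
      pairs = list(
        rd_pair("C", 1, 2, p$k1, p$k2, p$gamma1, p$K1edge, p$K1basal,
                beta = p$beta1, inhib = 3),
        rd_pair("I", 3, 4, p$k3, p$k4, p$gamma3, src1 = 1, hill = FALSE),
        rd_pair("R", 5, 6, p$k5, p$k6, p$gamma5, p$K5edge, p$K5basal,
                alpha = p$alpha5, src1 = 1)),
      totals = c(C = p$Ctc, I = p$Itc, R = p$Rtc),
      init = c(Ca = 0, Ci = p$Ctc, Ia = p$Itc / 2, Ii = p$Itc / 2,
               Ra = 0, Ri = p$Rtc),
      actin = "Ra", stimulus = list()),
    bidirectional = list(
      components = c("Ra", "Ri", "Ia", "Ii", "Ca", "Ci"),
      pairs = list(
        rd_pair("R", 1, 2, p$k1, p$k2, p$gamma1, p$K1edge, p$K1basal,
                alpha = p$alpha1, src1 = 5, beta = p$beta1, inhib = 3),
        rd_pair("I", 3, 4, p$k3, p$k4, p$gamma3, src1 = 1, hill = FALSE),
        rd_pair("C", 5, 6, p$k5, p$k6, p$gamma5, p$K5edge, p$K5basal,
                alpha = p$alpha5, src1 = 1)),
      totals = c(R = p$Rtc, I = p$Itc, C = p$Ctc),
      init = c(Ra = 0, Ri = p$Rtc, Ia = 0, Ii = p$Itc, Ca = 0, Ci = p$Ctc),
      actin = "Ra",
      # excitable variant: a point stimulus switches Cdc42 locally to the
      # active state; default location is one domain-edge pixel at angle 0
      stimulus = list(active = "Ca", inactive = "Ci", value = p$Ctc,
                      angle = 0)),
    upstream_effector = ,
    upstream_plus_feedback = list(
      components = c("Pa", "Pi", "Ia", "Ii", "Ca", "Ci", "Ra", "Ri"),
      pairs = list(
        rd_pair("P", 1, 2, p$k1, p$k2, p$gamma1, p$K1edge, p$K1basal,
                beta = p$beta1, inhib = 3),
        rd_pair("I", 3, 4, p$k3, p$k4, p$gamma3, src1 = 1, hill = FALSE),
        rd_pair("C", 5, 6, p$k5, p$k6, p$gamma5, p$K5edge, p$K5basal,
                alpha = p$alpha5, src1 = 1),
        rd_pair("R", 7, 8, p$k7, p$k8, p$gamma7, p$K7edge, p$K7basal,
                alpha = p$alpha7, src1 = 1,
                mu = if (is.null(p$mu7)) 0 else p$mu7,
                src2 = if (is.null(p$mu7)) 0L else 5L)),
      totals = c(P = p$Ptc, I = p$Itc, C = p$Ctc, R = p$Rtc),
      init = c(Pa = 0, Pi = p$Ptc, Ia = 0, Ii = p$Itc,
               Ca = 0, Ci = p$Ctc, Ra = 0, Ri = p$Rtc),
      actin = "Ra", stimulus = list())
  )

  diffusion <- vapply(spec$components, function(cc) p[[paste0("D_", cc)]],
                      numeric(1))
  new("ModelSpec", name = name, components = spec$components,
      pairs = spec$pairs, params = p, diffusion = diffusion,
      totals = spec$totals, init = spec$init,
      actinComponent = spec$actin, stimulus = spec$stimulus)
}

#' List the registered models
#'
#' @param verbose print components and defaults for each model.
#' @return Invisibly, the model names.
#' @export
listModels <- function(verbose = TRUE) {
  if (verbose) {
    for (nm in MODEL_NAMES) {
      m <- buildModel(nm)
      cat(nm, "\n  components: ", paste(m@components, collapse = ", "),
          "\n  defaults: ",
          paste(names(m@params), unlist(m@params), sep = "=", collapse = ", "),
          "\n", sep = "")
    }
  }
  invisible(MODEL_NAMES)
}

#' Spatial activation-threshold map
#'
#' Mask pixels with at least one 4-neighbor outside the mask (the one-pixel
#' boundary ring) receive the edge threshold; interior pixels the basal one.
#' At the defaults (K_edge = 1.4, K_basal = 2.1) the boundary ring operates in
#' the oscillatory regime while the interior is excitable, which localizes
#' transient activity patches at the cell edge.
#'
#' @param mask a \linkS4class{CellMask} or binary matrix.
#' @param Kedge,Kbasal threshold values (a.u.).
#' @return A \linkS4class{GridField} of thresholds (component \code{"K"}).
#' @export
thresholdMap <- function(mask, Kedge = 1.4, Kbasal = 2.1) {
  cm <- if (is(mask, "CellMask")) mask else cellMask(mask)
  m <- cm@mask
  edge <- cpp_edge_pixels(matrix(as.integer(m), nrow(m))) == 1L
  v <- matrix(NA_real_, nrow(m), ncol(m))
  v[m] <- Kbasal
  v[edge] <- Kedge
  gridField(v, cm, component = "K")
}

# R-side vectorized reaction evaluator (used by the 1D method-of-lines solver
# and by reaction-level tests). `Y`: nodes x components matrix; `K` a named
# per-pair threshold (scalar or per-node vector). Returns dY (nodes x comp).
reaction_rates <- function(model, Y, K = NULL) {
  dY <- matrix(0, nrow(Y), ncol(Y),
               dimnames = list(NULL, model@components))
  for (p in model@pairs) {
    xa <- Y[, p$a]; xi <- Y[, p$i]
    if (p$hill) {
      g <- p$gamma
      if (p$src1 > 0) g <- g + p$alpha * Y[, p$src1]^2
      if (p$src2 > 0) g <- g + p$mu * Y[, p$src2]^2
      Kp <- if (!is.null(K) && !is.null(K[[p$pair]])) K[[p$pair]] else p$Kbasal
      den <- Kp^2 + xa^2
      if (p$inhib > 0) den <- den + p$beta * Y[, p$inhib]^2
      rate <- (p$kon + g * xa^2 / den) * xi - p$koff * xa
    } else {
      s <- if (p$src1 > 0) Y[, p$src1] else 0
      rate <- (p$kon + p$gamma * s^2) * xi - p$koff * xa
    }
    dY[, p$a] <- dY[, p$a] + rate
    dY[, p$i] <- dY[, p$i] - rate
  }
  dY
}
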