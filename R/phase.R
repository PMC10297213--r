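# Dynamical-regime classification of the two-component MCRD core over the
# (gamma1, K1) plane and of the coupled GTPase-inhibitor system.

CORE_REGIMES <- c("no_pattern_high", "stimulus_induced_deactivation",
                  "turing_unstable", "stimulus_induced_activation",
                  "no_pattern_low")
COUPLED_REGIMES <- c("excitable", "oscillatory", "inactive")

#' Homogeneous steady states of the MCRD core
#'
#' All nonnegative roots of
#' \deqn{(k_1 + \gamma_1 G_a^2 / (K_1^2 + G_a^2)) (G_{tc} - G_a) - k_2 G_a = 0}
#' with \eqn{G_i = G_{tc} - G_a}, found by sign-change bracketing over
#' \eqn{[0, G_{tc}]} and polished with \code{uniroot}.
#'
#' @param k1,gamma1,K1,k2,Gtc kinetic parameters of the core (a.u.).
#' @param nGrid bracketing grid size.
#' @return data.frame with columns \code{Ga}, \code{Gi}, ordered by
#'   \code{Ga} (1 to 3 rows).
#' @examples
#' homogeneousSteadyStates(gamma1 = 0)  # unique root k1*Gtc/(k1+k2)
#' @export
homogeneousSteadyStates <- function(k1 = 0.005, gamma1 = 2, K1 = 2.1,
                                    k2 = 0.1, Gtc = 1, nGrid = 4000L) {
  if (Gtc <= 0) stop("Gtc must be positive")
  g <- function(Ga)
    (k1 + gamma1 * Ga^2 / (K1^2 + Ga^2)) * (Gtc - Ga) - k2 * Ga
  xs <- seq(0, Gtc, length.out = nGrid)
  vals <- g(xs)
  roots <- numeric()
  if (vals[1] == 0) roots <- c(roots, xs[1])
  for (q in seq_len(nGrid - 1L)) {
    if (vals[q] == 0 && q > 1) roots <- c(roots, xs[q])
    if (vals[q] * vals[q + 1L] < 0) {
      r <- uniroot(g, c(xs[q], xs[q + 1L]), tol = 1e-12)$root
      roots <- c(roots, r)
    }
  }
  if (vals[nGrid] == 0) roots <- c(roots, xs[nGrid])
  roots <- sort(unique(round(roots, 10)))
  data.frame(Ga = roots, Gi = Gtc - roots)
}

# partial derivatives of the net activation rate f(Ga, Gi) at a state
core_jacobian <- function(Ga, Gi, k1, gamma1, K1, k2) {
  den <- K1^2 + Ga^2
  fa <- gamma1 * Gi * 2 * Ga * K1^2 / den^2 - k2
  fi <- k1 + gamma1 * Ga^2 / den
  c(fa = fa, fi = fi)
}

# maximal linear growth rate of spatial modes q in (0, pi/dx] for the
# mass-conserved pair linearized at (Ga*, Gi*)
lateral_growth <- function(Ga, Gi, k1, gamma1, K1, k2, D_Ga, D_Gi,
                           dx = 0.02, nq = 400L) {
  J <- core_jacobian(Ga, Gi, k1, gamma1, K1, k2)
  qs <- seq(1e-3, pi / dx, length.out = nq)
  gmax <- -Inf
  for (q in qs) {
    A <- matrix(c(J["fa"] - D_Ga * q^2, -J["fa"],
                  J["fi"], -J["fi"] - D_Gi * q^2), 2, 2)
    gmax <- max(gmax, max(Re(eigen(A, only.values = TRUE)$values)))
  }
  gmax
}

#' Classify the dynamical regime of the MCRD core
#'
#' Labels a point of the (gamma1, K1) plane by (i) the count of homogeneous
#' steady states and (ii) a lateral-instability test (growth of the fastest
#' spatial mode of the mass-conserved pair, linearized at the resting state
#' reached from the low-activity initial condition). The five regimes are:
#' stable high/low homogeneous state with no stimulus response
#' (\code{no_pattern_high}/\code{no_pattern_low}), bistable-like threshold
#' response (\code{stimulus_induced_deactivation}/\code{..._activation}), and
#' the \code{turing_unstable} regime where patterns grow from any small
#' perturbation.
#'
#' @inheritParams homogeneousSteadyStates
#' @param D_Ga,D_Gi diffusion coefficients (must satisfy D_Ga < D_Gi).
#' @param dx spatial resolution bounding the admissible wavenumbers.
#' @param growthTol instability threshold on the maximal growth rate.
#' @return One of the five regime labels.
#' @export
classifyCoreRegime <- function(k1 = 0.005, gamma1 = 2, K1 = 2.1, k2 = 0.1,
                               Gtc = 1, D_Ga = 0.001, D_Gi = 0.13, dx = 0.02,
                               growthTol = 1e-6) {
  if (k1 == 0 && gamma1 == 0 && k2 == 0)
    stop("degenerate parameters: all rates zero")
  if (D_Ga >= D_Gi)
    stop("requires D_Ga < D_Gi (active form diffuses slower)")
  ss <- homogeneousSteadyStates(k1, gamma1, K1, k2, Gtc)
  # resting state: from the homogeneous low-activity initial condition the
  # well-mixed system flows to the smallest root
  rest <- ss[1, ]
  growth <- lateral_growth(rest$Ga, rest$Gi, k1, gamma1, K1, k2, D_Ga, D_Gi,
                           dx)
  high <- rest$Ga >= 0.5 * Gtc
  if (growth > growthTol) return("turing_unstable")
  if (nrow(ss) >= 3L)
    return(if (high) "stimulus_induced_deactivation"
           else "stimulus_induced_activation")
  if (high) "no_pattern_high" else "no_pattern_low"
}

# count completed activity pulses (spatial max of the active form crossing a
# threshold upward then downward) in a solveRD1D output
count_pulses <- function(sol, component, threshold) {
  m <- apply(sol$profiles[, component, , drop = FALSE], 3, max)
  above <- m > threshold
  ups <- which(diff(above) == 1L)
  downs <- which(diff(above) == -1L)
  if (above[1]) ups <- c(0L, ups)  # starts above: count the opening pulse
  pulses <- 0L
  for (u in ups) if (any(downs > u)) pulses <- pulses + 1L
  list(pulses = pulses, anyActivity = any(above), maxTrace = m)
}

#' Classify the coupled GTPase-inhibitor system
#'
#' Simulates the four-component system in 1D from a near-homogeneous initial
#' condition. \code{oscillatory}: at least \code{minPulses} recurring activity
#' pulses without stimulus. \code{excitable}: quiescent without stimulus, but
#' a finite stimulus (active GTPase raised to 20 on the left 2.5\% of the
#' domain) elicits exactly one pulse followed by decay. \code{inactive}
#' otherwise (including a persistent pattern that is never extinguished).
#'
#' @param model a \linkS4class{ModelSpec} of the \code{gtpase_inhibitor} form
#'   (first pair = GTPase, second = inhibitor).
#' @param K1 activation threshold used (spatially uniform in 1D).
#' @param tWindow simulation window (a.u.); 5e4 reproduces the reference
#'   operating points, smaller windows suffice for quick checks.
#' @param nodes spatial nodes.
#' @param nOut saved time points.
#' @param minPulses pulse count required to call the dynamics oscillatory.
#' @param seed seed for the initial perturbation.
#' @return \code{"oscillatory"}, \code{"excitable"} or \code{"inactive"}.
#' @export
classifyCoupledRegime <- function(model = buildModel("gtpase_inhibitor"),
                                  K1 = NULL, tWindow = 5e4, nodes = 200L,
                                  nOut = 1000L, minPulses = 3L, seed = 1L) {
  gp <- model@pairs[[1]]
  K <- if (is.null(K1)) NULL else setNames(K1, gp$pair)
  thr <- 0.5 * model@totals[[gp$pair]]
  act <- model@components[gp$a]
  free <- solveRD1D(model, tEnd = tWindow, nOut = nOut, nodes = nodes, K = K,
                    perturb = 1e-6, seed = seed)
  pf <- count_pulses(free, act, thr)
  if (pf$pulses >= minPulses) return("oscillatory")
  if (!pf$anyActivity) {
    # quiescent: probe excitability with a mass-conserving localized stimulus
    # (active form at 20 on the left 2.5% of the domain, inactive form at
    # half the total everywhere, so the pair total stays at its nominal value)
    inact <- model@components[gp$i]
    tot <- model@totals[[gp$pair]]
    nstim <- max(1L, floor(0.025 * nodes))
    init <- as.list(model@init)
    prof <- rep(0, nodes)
    prof[seq_len(nstim)] <- tot / 2 * nodes / nstim
    init[[act]] <- prof
    init[[inact]] <- rep(tot / 2, nodes)
    stim <- solveRD1D(model, init = init, tEnd = tWindow, nOut = nOut,
                      nodes = nodes, K = K, perturb = 1e-6, seed = seed)
    ps <- count_pulses(stim, act, thr)
    if (ps$pulses == 1L && !tail(ps$maxTrace > thr, 1)) return("excitable")
  }
  "inactive"
}

#' Activation delay between two components in a 1D run
#'
#' Simulates the model in 1D at the oscillatory threshold, takes the
#' spatial-maximum time series of the two active forms, and measures when
#' each component activates in every pulse cycle: the upward crossing of a
#' threshold placed a fixed fraction into the component's own dynamic range.
#' The delay is the mean time from a \code{comp1} activation to the nearest
#' \code{comp2} activation (positive when comp2 activates after comp1). This
#' onset-based definition is insensitive to the very different pulse shapes
#' of a persistently polarized Cdc42 patch (slow amplitude modulation) and
#' an all-or-none Rac1 pulse, and is the quantity the Cdc42-to-Rac1 feedback
#' gain \code{mu7} compensates.
#'
#' @param model a \linkS4class{ModelSpec} containing both components.
#' @param comp1,comp2 active-form component ids (delay of comp2 after comp1).
#' @param K threshold selector passed to \code{\link{solveRD1D}} (default
#'   \code{"edge"}, the oscillatory operating point).
#' @param tWindow simulated time (a.u.); the initial transient is discarded.
#' @param transient initial fraction of the series discarded.
#' @param nodes,nOut discretization of \code{\link{solveRD1D}}.
#' @param onsetFrac fraction of the dynamic range defining the activation
#'   threshold.
#' @param maxGap onsets farther apart than this (a.u.) are not paired.
#' @param seed initial-perturbation seed.
#' @return The mean delay in a.u. (resolution \code{tWindow/nOut}).
#' @export
activationDelay1D <- function(model, comp1 = "Ca", comp2 = "Ra", K = "edge",
                              tWindow = 6000, transient = 0.25, nodes = 100L,
                              nOut = 3000L, onsetFrac = 0.25, maxGap = 120,
                              seed = 1L) {
  sol <- solveRD1D(model, tEnd = tWindow, nOut = nOut, nodes = nodes, K = K,
                   perturb = 1e-6, seed = seed)
  keep <- which(sol$times > transient * tWindow)
  a <- apply(sol$profiles[, comp1, keep, drop = FALSE], 3, max)
  b <- apply(sol$profiles[, comp2, keep, drop = FALSE], 3, max)
  if (diff(range(a)) < 1e-6 || diff(range(b)) < 1e-6)
    stop("no activity pulses: delay undefined")
  dtOut <- tWindow / nOut
  onset_times <- function(x) {
    thr <- min(x) + onsetFrac * (max(x) - min(x))
    which(diff(x > thr) == 1L) * dtOut
  }
  oa <- onset_times(a)
  ob <- onset_times(b)
  if (!length(oa) || !length(ob))
    stop("no activation onsets detected: delay undefined")
  d <- vapply(oa, function(t1) {
    gaps <- ob - t1
    gaps <- gaps[abs(gaps) <= maxGap]
    if (!length(gaps)) NA_real_ else gaps[which.min(abs(gaps))]
  }, numeric(1))
  if (all(is.na(d))) stop("no paired activation onsets within maxGap")
  mean(d, na.rm = TRUE)
}

#' Sweep the (gamma1, K1) plane of the MCRD core
#'
#' @param gamma1s,K1s parameter grids.
#' @param ... further arguments to \code{\link{classifyCoreRegime}}.
#' @return data.frame with columns \code{gamma1}, \code{K1}, \code{regime}.
#' @export
phaseDiagram <- function(gamma1s = seq(0.2, 6, length.out = 15),
                         K1s = seq(0.2, 6, length.out = 15), ...) {
  grid <- expand.grid(gamma1 = gamma1s, K1 = K1s)
  grid$regime <- vapply(seq_len(nrow(grid)), function(q)
    classifyCoreRegime(gamma1 = grid$gamma1[q], K1 = grid$K1[q], ...),
    character(1))
  grid
}

#' Render a phase diagram to PNG
#'
#' @param pd output of \code{\link{phaseDiagram}}.
#' @param file PNG path.
#' @return Invisibly, \code{file}.
#' @export
plotPhaseDiagram <- function(pd, file) {
  g1 <- sort(unique(pd$gamma1)); K1 <- sort(unique(pd$K1))
  z <- matrix(match(pd$regime, CORE_REGIMES),
              length(g1), length(K1))[order(order(g1)), ]
  grDevices::png(file, width = 640, height = 560)
  on.exit(grDevices::dev.off())
  cols <- c("#d73027", "#fc8d59", "#fee090", "#91bfdb", "#4575b4")
  graphics::image(g1, K1, z, col = cols, zlim = c(1, 5),
                  xlab = expression(gamma[1]), ylab = expression(K[1]),
                  main = "MCRD core regimes")
  graphics::legend("topright", legend = CORE_REGIMES, fill = cols, cex = 0.7)
  invisible(file)
}
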