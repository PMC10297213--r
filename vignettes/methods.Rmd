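---
title: "Coupled reaction-diffusion and cell morphodynamics: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled reaction-diffusion and cell morphodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(morphoRD)
```

# Overview

morphoRD couples three layers that together simulate and quantify cell
membrane ruffling:

1. **Signaling** — mass-conserved reaction-diffusion (MCRD) models of
   Rho-GTPase activity. Each protein exists in a slow-diffusing,
   membrane-bound active form and a fast-diffusing cytosolic inactive form;
   interconversion conserves the total amount of each protein.
2. **Morphodynamics** — a stochastic pixel-grid engine in which the binary
   cell mask gains pixels (protrusion) and loses pixels (retraction), with
   per-pixel event probabilities combining local curvature, a cell-volume
   homeostat, and the local actin-polymerization drive read from the RD
   state.
3. **Edge analysis** — a mid-contour pipeline that turns any time-lapse of
   masks plus a biosensor channel (simulated or experimental) into edge
   trajectories, velocity/signal kymographs and velocity-peak-aligned
   statistics.

The scientific question the package is built around: is membrane protrusion
controlled by the *level* of active GTPase, or by its *rate of activation*?
The two hypotheses enter only through the actin factor of the morphodynamic
engine (`actinMode = "concentration"` vs `"rate"`), and the edge pipeline
measures the timing signature each produces.

# The signaling models

The core motif is a two-component MCRD pair (`buildModel("mcrd_single")`):

$$\partial_t G_a = \Big(k_1 + \frac{\gamma_1 G_a^2}{K_1^2 + G_a^2}\Big) G_i
  - k_2 G_a + D_{G_a}\nabla^2 G_a,$$

with the mirrored equation for $G_i$ so that $G_a + G_i$ is conserved.
Autocatalysis (the Hill term) plus the diffusion contrast
$D_{G_a} = 0.001 \ll D_{G_i} = 0.13$ produce wave-pinning: localized
activity patches that stop moving instead of sweeping the domain. Defaults:
$k_1 = 0.005$, $\gamma_1 = 2$, $k_2 = 0.1$, total concentration 1.

Five extensions are registered (see `?buildModel`): a GTPase + inhibitor
system in which the inhibitor raises the activation threshold
($K_1^2 \to K_1^2 + \beta_1 I_a^2$) and thereby extinguishes patches;
Cdc42-driven Rac1; bidirectionally coupled Rac1/Cdc42; and two variants in
which a common upstream effector (conceptually, PI3K-generated
phosphoinositides) drives both GTPases, optionally with a Cdc42-to-Rac1
feedback gain $\mu_7$. Cross-coupling terms such as $\alpha_5 C_s^2$ read
the *local, instantaneous* active-form concentration at the same pixel; no
spatial or temporal smoothing is applied, since none is defined by the
model equations.

**Edge/basal threshold.** On 2D masks the activation threshold takes the
value $K_\mathrm{edge} = 1.4$ on the one-pixel boundary ring of the mask and
$K_\mathrm{basal} = 2.1$ in the interior (`thresholdMap`), reflecting
curvature-sensing GEFs that keep the cell edge more excitable. At these
values the boundary ring operates in the oscillatory regime and the interior
in the excitable regime, so transient activity patches form at, and stay
near, the cell edge. The map is recomputed after every mask change.

# Dynamical-regime classification

`homogeneousSteadyStates()` finds all roots of the well-mixed balance by
sign-change bracketing plus root polishing. `classifyCoreRegime()` labels a
$(\gamma_1, K_1)$ point using (i) the root count and (ii) a lateral
(Turing-type) instability test: the growth rate of spatial modes
$q \in (0, \pi/\Delta x]$ of the mass-conserved pair linearized at the
resting state, with instability declared above a growth rate of $10^{-6}$.
Bistable root structures give the stimulus-induced labels; the high/low
distinction uses the resting active fraction relative to half the total.
The region boundaries are validated against the two printed operating
points and a direct 1D simulation oracle (patterns growing from $10^{-6}$
perturbations), not against any closed-form bifurcation analysis — formal
continuation is out of scope.

`classifyCoupledRegime()` runs the four-component GTPase-inhibitor system in
1D: at least three completed activity pulses without stimulus is
*oscillatory*; quiescence plus exactly one stimulus-elicited pulse is
*excitable*; anything else (including a never-extinguished patch when the
inhibitor is disabled) is *inactive*. The stimulus raises the active form to
20 on the left 2.5% of the domain while setting the inactive form to half
the total everywhere — this keeps the pair total at its nominal value, which
matters: a stimulus that adds mass moves the system to a different (richer)
total and can spuriously convert an excitable point into a self-sustained
oscillator.

# Numerical scheme

**2D.** Forward Euler with the five-point Laplacian; no-flux boundaries are
implemented with mirror ghost values, which makes the discrete total flux
across the mask boundary exactly zero (so conservation holds to floating
precision). The grid spacing is $\Delta x = 0.02$ a.u.

The reference explicit-scheme settings for this model family quote
$\Delta t = 10^{-3}$, but the 2D von Neumann bound for the five-point
stencil requires $\Delta t\, D_\mathrm{max} / \Delta x^2 < 1/4$, and
$10^{-3} \cdot 0.13 / 0.02^2 = 0.325$ exceeds it — the scheme then amplifies
checkerboard modes by $-1.6$ per step and blows up within tens of
iterations. morphoRD therefore uses $\Delta t = 5 \times 10^{-4}$ (Courant
number 0.1625) and keeps the *physical* cadence of all other quantities:
100 RD iterations per protrusion-retraction cycle (0.05 a.u.) and one saved
frame per 2000 iterations (1 a.u.). `solverConfig()` enforces the bound
(0.25 on 2D domains, 0.5 on 1-pixel strips, where the scheme is effectively
one-dimensional).

**Noise.** Intrinsic signaling noise enters as one draw per conserved pair
per pixel per step, added to the active and subtracted from the inactive
form, so pair totals are conserved exactly; a positivity guard skips the
draw when it would push either form negative. The reference noise condition
is amplitude 5 with Euler increments at $\Delta t = 10^{-3}$, i.e. a
variance rate of $\Delta t\,\alpha^2 = 0.025$ per a.u. Because the default
increment scaling is literal-Euler ($\Delta t\,\alpha\,\xi$; a
`sqrt_dt` switch selects Euler-Maruyama scaling instead), keeping
$\alpha = 5$ at a finer step would *weaken* the noise. `solverConfig()`
therefore rescales the default amplitude by $\sqrt{10^{-3}/\Delta t}$
($\approx 7.07$ at the default step), which reproduces the reference
stochastic process independently of the step and reduces to $\alpha = 5$ at
$\Delta t = 10^{-3}$. The draws come from a dedicated xoshiro256++/ziggurat
stream seeded by `solverConfig(seed=)`, so runs are exactly reproducible;
roughly $10^9$ draws occur per minute-scale simulation, which is why the
stream lives in C++.

**1D.** `solveRD1D()` uses a stiff-capable method of lines
(`deSolve::ode.1D`, lsoda, banded Jacobian) on 400 nodes over the default
4 a.u. domain, relative tolerance $10^{-6}$. The 2D stepper restricted to a
$1 \times N$ strip agrees with it to better than $10^{-3}$ relative L2 at
$t = 10$ a.u., which is the package's main two-route solver cross-check.

# The morphodynamic engine

Event probabilities are products of three factors, all in $[0, 1]$:

* **Geometry** (`geometryFactor`): the distance-weighted fraction of
  like pixels in the candidate's 8-neighborhood, raised to the power $k$:
  $w = \big(\sum m' d^{-g} / \sum d^{-g}\big)^k$ with $d \in \{1,
  \sqrt 2\}$, $g = 2$, $k = 3$. Convex bumps protrude less and retract
  more; concavities fill in. The printed form of this factor is
  typographically ambiguous about how $g$ and $k$ combine; morphoRD groups
  it as a normalized weighted neighbor fraction raised to $k$, because the
  accompanying text assigns $g$ to distance (curvature) sensitivity and $k$
  to outline smoothness — and a hand-computed example
  ($w = (1/3)^3$ for a flat-edge candidate) is frozen in the tests.
* **Volume** (`volumeFactor`): a sigmoid in $V - V_0$ with sharpness
  $10^{-3}$ and deviations $\beta_V = \gamma_V = 0.5$; cells grown past
  $V_0$ protrude less and retract more. (The saturating value for a grown
  cell is $1/2 - \gamma_V$ for protrusion; an inline limit in the source
  text that states $1/2 + \gamma_V$ contradicts its own formula and prose
  and is not followed.)
* **Actin** (`actinFactor`): a sigmoid in the local drive $A$ with
  threshold `Aact`; with $\beta_A = 0$ the factor is neutral (0.5) below
  threshold and shifts to $1/2 + \gamma_A$ (protrusion) and $1/2 -
  \gamma_A$ (retraction) above it. In `"concentration"` mode $A$ is the
  active-form concentration; in `"rate"` mode it is the finite-difference
  temporal derivative over one protrusion-retraction cycle (0.05 a.u.),
  the smallest interval at which the engine samples the RD state. For
  background candidates $A$ is extrapolated as the mean over in-mask
  8-neighbors. Per-model actin parameters are in `actinPreset()`.

**Topology guard.** Accepted events are committed one at a time in random
order; each commit must keep the mask foreground 4-connected, the background
4-connected (no holes), and free of corner-only diagonal contacts. The test
is local (Yokoi connectivity numbers of the foreground and background
patterns in the 3x3 neighborhood plus a corner-touch rule), so of two
simultaneously accepted diagonal events that would pinch the mask, exactly
one survives. Retraction additionally never shrinks the mask below
`minPixels` (default 20), and protrusion never reaches the frame border.

**Mass redistribution** (`redistributeMass`): new pixels are initialized
with their old-mask neighborhood mean and that mass is subtracted evenly
from the whole new mask (skipping pixels that would go negative, iterating
on the remainder, so conservation is exact to floating precision); removed
pixels' mass is added evenly. Growth therefore dilutes concentrations while
total mass is invariant. New pixels are excluded from contributing a
spurious spike to the rate-mode drive by resetting their rate baseline at
initialization.

A simulation step is: one protrusion event sweep, one retraction event
sweep, redistribution after each, threshold-map refresh, then one
protrusion-retraction cycle's worth of RD iterations. `simulateCell()`
repeats this and saves one frame per 1 a.u.; `burnIn` frames can be
discarded so that analyses see statistically stationary ruffling rather
than the ignition transient of the pattern-forming system (patches need
$\mathcal{O}(100)$ a.u. to grow out of the noise floor from homogeneous
initial conditions).

# The edge pipeline

`normalizeBiosensor()` clips the series at median $\pm$ 6 MAD (plain median
absolute deviation, computed over in-mask pixels when a mask is supplied —
simulated stacks are zero outside the cell and would otherwise corrupt the
statistics) and min-max scales to $[0,1]$. An optional sparse-outlier rule
(drop pixels outside median $\pm 5$ from the min/max computation when fewer
than 20 exist) is off by default; its printed description does not state
the units of the $\pm 5$ band, so it is exposed but not relied upon.

`windowContours()` splits the series into 20-frame windows; the outer/inner
contours bound the union/intersection of the window's masks, resampled at
1 px arc length. `midContour()` alternates normal-midpoint sweeps between
the two contours until their average point-to-polyline distance falls below
0.1 px. Two robustness measures matter on staircase pixel contours: normals
are computed from tangents of a 5-point smoothed copy of the contour (the
contour points themselves are not displaced, so no shrink bias), and
intersections farther than three times the current inter-contour distance
are discarded — without these, midpoint scatter produces self-intersecting
polygons whose resampled point count explodes and the iteration cannot
converge. On clean annuli (concentric circles 10 px/20 px) the construction
lands within 0.2 px of the central circle in a couple of iterations.

`buildTrajectories()` drops a normal segment through every mid-contour
vertex, clipped to the inner/outer band (with a fallback band and a 5-px
per-frame trust radius: an outline intersection that jumps farther than
that in one frame is a different outline branch, and the frame is treated
as missing; single-frame gaps are interpolated, longer gaps truncate the
trajectory). Across windows, trajectories continue by greedy
nearest-endpoint matching with the same 5-px cap. Velocity is the signed
per-frame displacement along the outward normal (protrusion positive);
signal is the mean normalized intensity over the in-mask disc of radius
2 px around each trajectory point.

`peakAlignedAnalysis()` implements the printed recipe: drop trajectories
with any $|v| > 20$ SD; threshold the velocity kymograph at median
$- 2\,\mathrm{MAD}$ (the printed sign; `peakRule = "plus"` selects the
physically plausible median $+ 2\,\mathrm{MAD}$ variant, under which
regions are sparse islands of genuinely high velocity); keep connected
regions of at least 10 pixels; take strict 2D local maxima inside them; and
average $\pm 20$-frame windows of velocity and signal across peaks with
97.5% normal-approximation confidence half-widths
($\bar x \pm z_{0.975}\,s/\sqrt n$). The signal derivative is the
difference from the previous frame; the edge coordinate is the cumulative
sum of the velocity trace. The reported `lag` is the frame offset of the
signal-trace maximum.

`calibrateUnits()` matches temporal and spatial decorrelation scales (first
crossing of the autocorrelation below $1/e$) between simulated and
experimental velocity kymographs; without experimental input it returns the
stored reference constants 0.65 s and 10.127 um per a.u.

# The timing signature, and what desk-scale runs do and do not show

With rate-regulated actin the edge protrudes while activity *grows*, so the
activity peak trails the velocity peak; with concentration regulation the
two should coincide. At desk scale this signature competes with two
systematic mechanisms that make the aligned signal *decline* through the
peak window regardless of regulation mode: the advancing edge converts its
own oscillatory boundary ring to the basal threshold (eroding the patch
that drove it), and mask growth dilutes all concentrations (mass is
conserved, concentrations are not). Both are genuine model mechanisms, and
both scale inversely with cell size — the dilution per event is the added
mass over the whole cell area, and the volume homeostat responds to the
absolute pixel excess. In radius-40 cells (the package default, ~5000 px)
the rate-mode signature wins: the peak-aligned signal keeps rising after
the velocity peak and the lag is strongly positive (~+15-20 frames, the
patch growth half-time). In radius-30 cells the decline mechanisms dominate
both modes and the measured lag reflects the random phase of the global
pulse cycle at each seed. The concentration-mode arm never reads "lag 0" at
the 1 a.u. frame cadence: its within-patch timing structure spans +-15-20
a.u., which only collapses below one frame at the 10 a.u. recording step
used for the reference analyses (where a concentration-mode lag of 0 was
measured during development) — but at that step the rate-mode lag also
shrinks to 1-2 frames and is masked by the zero-lag sampling correlation.
The two sub-claims therefore do not hold at any single desk-scale cadence.
The tests run the default cadence and geometry, where the rate arm is
expected to pass and the concentration arm is reported honestly as failing,
with this analysis as the explanation. A full-scale reproduction (larger
cell, 10 a.u. recording, peaks drawn from genuinely high-velocity regions
rather than noise maxima) is a matter of computation time, not of model
capability.

The synthetic ruffling fixture (`makeRufflingStack`) sidesteps the coupled
dynamics entirely: it prescribes boundary oscillation within angular lobes
and paints the *known* delayed velocity into a band inside the edge, so
pipeline lag recovery (0, 3, 8 frames recovered within 1 frame) is a pure
validation of the measurement chain. What the fixture does not emulate:
signal produced by reaction-diffusion (its signal is exactly the delayed
velocity), segmentation errors, photobleaching, or background structure —
passing fixtures validates the pipeline's geometry and timing, not its
behavior on raw microscope data.

# Delay compensation between Cdc42 and Rac1

In the upstream-effector-plus-feedback model the Cdc42 component settles
into a persistently polarized patch whose spatial maximum is only
amplitude-modulated, while Rac1 fires all-or-none pulses. The literal
peak-time difference of such differently shaped traces mostly measures
pulse asymmetry, so `activationDelay1D()` measures *activation onsets*
instead: upward crossings of a threshold placed 25% into each component's
own dynamic range, paired per pulse cycle. Under this measure Rac1
activates ~50 a.u. after Cdc42 without feedback, and the delay decreases
strictly as the feedback gain $\mu_7$ grows (49.8, 43.3, 37.3 a.u. at
$\mu_7 = 0, 0.03, 0.06$) — the compensation mechanism, reproduced
monotonically as the tests require.

# Problem sizes used by the tests

Simulations in the test-suite run at the sizes a laptop handles in minutes:
100x100 grids with radius 25-40 cells, 40-250 saved frames, 1D runs of
5x10^4 a.u. on 200 nodes, and three seeds where stochastic medians are
asserted. These are the package's chosen desk-scale study conditions; the
full-scale counterparts (200x200 grids, 5x10^5 a.u. 1D windows, 10 a.u.
recording over thousands of a.u.) change no code path, only runtime.

# Known limitations

* Broad lamellipodia-like ruffling only; filopodia-scale protrusions,
  membrane folds, and mechanics (forces, viscoelasticity) are out of scope.
* Segmentation of raw fluorescence into masks is only a convenience
  (`maskFromIntensity`); the pipeline contract starts from masks.
* Regime boundaries in the $(\gamma_1, K_1)$ plane are defined by the
  linearized test and validated against simulation, not by formal
  bifurcation continuation.
* The explicit 2D scheme is fixed-step; no implicit or adaptive variants.
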