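# Masked Laplacian, explicit 2D stepping, and the 1D method-of-lines solver.

test_that("masked Laplacian implements the no-flux five-point stencil", {
  m <- discMask(16, 16, 5)
  mk <- maskMatrix(m)

  # constant field has zero Laplacian under no-flux boundaries
  f <- gridField(matrix(3.7, 16, 16), m)
  L <- maskedLaplacian(f, dx = 0.5)
  expect_equal(max(abs(fieldValues(L)[mk])), 0)

  # divergence theorem: total flux vanishes for arbitrary fields
  set.seed(42)
  v <- matrix(runif(256), 16, 16)
  L2 <- maskedLaplacian(v, m, dx = 0.2)
  expect_lt(abs(sum(L2[mk]) * 0.2^2), 1e-10)

  # single interior unit pixel, dx = 1: -4 at the pixel, +1 at 4-neighbors
  full <- cellMask(rbind(0, cbind(0, matrix(1, 5, 5), 0), 0))
  v3 <- matrix(0, 7, 7); v3[4, 4] <- 1
  L3 <- maskedLaplacian(v3, full, dx = 1)
  expect_equal(L3[4, 4], -4)
  expect_equal(L3[3, 4], 1)
  expect_equal(L3[4, 3], 1)
  expect_equal(L3[5, 4], 1)
  expect_equal(L3[4, 5], 1)

  expect_error(maskedLaplacian(v3, matrix(0L, 7, 7), dx = 1), "empty mask")
})

test_that("2D stepping conserves pairwise mass and fixes homogeneous states", {
  mod <- buildModel("gtpase_inhibitor")
  m <- discMask(40, 40, 14)
  mk <- maskMatrix(m)
  f0 <- morphoRD:::initFields2D(mod, m)

  # homogeneous state with gamma terms off is a fixed point at alpha = 0
  modFlat <- buildModel("gtpase_inhibitor",
                        overrides = list(gamma1 = 0, gamma3 = 0))
  ss <- homogeneousSteadyStates(k1 = 0.005, gamma1 = 0, K1 = 2.1, k2 = 0.1)
  fss <- f0
  fss$Ga[mk] <- ss$Ga; fss$Gi[mk] <- ss$Gi
  ia <- 3 * 1e-5 / (1e-5 + 1e-2)  # inhibitor linear steady state
  fss$Ia[mk] <- ia; fss$Ii[mk] <- 3 - ia
  out <- rdStep2D(fss, m, modFlat, solverConfig(noiseAmp = 0), nsteps = 200)
  expect_equal(out$Ga[mk], fss$Ga[mk], tolerance = 1e-9)
  expect_equal(out$Ia[mk], fss$Ia[mk], tolerance = 1e-9)

  # pairwise mass conservation with full noise, per step tolerance 1e-10
  cfg <- solverConfig(seed = 5)
  f1 <- rdStep2D(f0, m, mod, cfg, nsteps = 500)
  for (p in list(c("Ga", "Gi"), c("Ia", "Ii"))) {
    m0 <- sum(f0[[p[1]]][mk] + f0[[p[2]]][mk])
    m1 <- sum(f1[[p[1]]][mk] + f1[[p[2]]][mk])
    expect_lt(abs(m1 - m0) / m0, 1e-10)
  }

  # positivity after stepping
  expect_true(all(vapply(f1, function(x) all(x[mk] >= 0), logical(1))))

  # alpha = 0 is bit-for-bit reproducible
  a <- rdStep2D(f0, m, mod, solverConfig(noiseAmp = 0), nsteps = 50)
  b <- rdStep2D(f0, m, mod, solverConfig(noiseAmp = 0), nsteps = 50)
  expect_identical(a, b)
})

test_that("free diffusion of a bump spreads with variance ~ 2 D t", {
  # reactions disabled: only the active form diffuses a Gaussian bump
  mod <- buildModel("mcrd_single",
                    overrides = list(k1 = 0, gamma1 = 0, k2 = 0,
                                     D_Ga = 0.01, D_Gi = 0.13))
  n <- 61L
  m <- cellMask(rbind(0, cbind(0, matrix(1, n - 2, n - 2), 0), 0))
  mk <- maskMatrix(m)
  dx <- 0.02
  ctr <- (n + 1) / 2
  xs <- (seq_len(n) - ctr) * dx
  s0 <- 0.05
  g <- outer(xs, xs, function(a, b) exp(-(a^2 + b^2) / (2 * s0^2)))
  f <- list(Ga = g, Gi = matrix(0.5, n, n))
  tEnd <- 0.2
  cfg <- solverConfig(noiseAmp = 0, dt = 5e-4)
  out <- rdStep2D(f, m, mod, cfg, nsteps = as.integer(tEnd / cfg@dt))
  w <- out$Ga[mk] / sum(out$Ga[mk])
  xg <- matrix(xs, n, n)[mk]; yg <- matrix(xs, n, n, byrow = TRUE)[mk]
  varObs <- sum(w * (xg^2 + yg^2)) -
    sum(w * xg)^2 - sum(w * yg)^2
  varExp <- 2 * s0^2 + 4 * 0.01 * tEnd  # per-axis s0^2 + 2 D t, two axes
  expect_equal(varObs, varExp, tolerance = 0.05)
})

test_that("1D solver conserves total GTPase and pins heterogeneous fronts", {
  mod <- buildModel("mcrd_single")

  # monostable region: homogeneous init converges to the steady state
  modMono <- buildModel("mcrd_single", overrides = list(gamma1 = 0))
  sol <- solveRD1D(modMono, tEnd = 500, nOut = 5, nodes = 100, perturb = 0)
  expect_equal(unname(sol$profiles[, "Ga", 6]),
               rep(0.005 / 0.105, 100), tolerance = 1e-4)

  # total concentration Ga + Gi stays at Gt.c. = 1 at every output time
  sol2 <- solveRD1D(mod, tEnd = 200, nOut = 8, nodes = 120, perturb = 1e-6)
  for (ti in seq_along(sol2$times)) {
    tot <- sol2$profiles[, "Ga", ti] + sol2$profiles[, "Gi", ti]
    expect_equal(mean(tot), 1, tolerance = 1e-6)
  }

  # wave pinning: heterogeneous init forms a stationary front
  init <- list(Ga = c(rep(20, 3), rep(0, 117)), Gi = rep(0.5, 120))
  sol3 <- solveRD1D(mod, init = init, tEnd = 4000, nOut = 8, nodes = 120,
                    perturb = 0)
  p <- sol3$profiles
  # pattern present (front separates high and low plateaus)...
  expect_gt(max(p[, "Ga", 9]), 1.5)
  expect_lt(min(p[, "Ga", 9]), 0.2)
  # ...and stationary: late-time drift is negligible
  drift <- sqrt(mean((p[, "Ga", 9] - p[, "Ga", 8])^2)) /
    sqrt(mean(p[, "Ga", 9]^2))
  expect_lt(drift, 1e-3)
})

test_that("2D stepping on a strip matches the 1D method of lines", {
  # uniform threshold: on a 1xN strip every pixel is an edge pixel, so the
  # edge value must equal the basal value used by the 1D solver
  mod <- buildModel("mcrd_single", overrides = list(K1edge = 2.1))
  nodes <- 200L
  dx <- 0.02
  # heterogeneous, smooth initial profile away from steady state
  x <- (seq_len(nodes) - 0.5) * dx
  ga0 <- 0.4 + 0.3 * cos(pi * x / 4)
  gi0 <- 1 - ga0

  strip <- matrix(TRUE, 1, nodes)
  f <- list(Ga = matrix(ga0, 1), Gi = matrix(gi0, 1))
  cfg <- solverConfig(noiseAmp = 0, dt = 5e-4, dx = dx)
  out <- rdStep2D(f, strip, mod, cfg, nsteps = as.integer(10 / cfg@dt))

  sol <- solveRD1D(mod, init = list(Ga = ga0, Gi = gi0), tEnd = 10,
                   nOut = 1, nodes = nodes, perturb = 0,
                   rtol = 1e-8, atol = 1e-10)
  rel <- sqrt(mean((out$Ga[1, ] - sol$profiles[, "Ga", 2])^2)) /
    sqrt(mean(sol$profiles[, "Ga", 2]^2))
  expect_lt(rel, 1e-3)
})

test_that("solver input validation catches bad states", {
  mod <- buildModel("mcrd_single")
  m <- discMask(10, 10, 3)
  f <- morphoRD:::initFields2D(mod, m)
  f$Ga[maskMatrix(m)][1] <- -0.1
  f$Ga[5, 5] <- -0.1
  expect_error(rdStep2D(f, m, mod, solverConfig(), nsteps = 1), "negative")
  expect_error(solveRD1D(mod, domainLength = -1), "positive")
  expect_error(rdStep2D(morphoRD:::initFields2D(mod, m), m, mod,
                        solverConfig(dt = 0.01), nsteps = 1), "unstable")
})
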