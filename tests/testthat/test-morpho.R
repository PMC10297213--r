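# Probability factors, topology-guarded protrusion/retraction events, mass
# redistribution and the coupled simulation loop.

test_that("geometry factor matches hand-computed stencil values", {
  # flat half-plane: background candidate directly above the edge sees one
  # orthogonal and two diagonal mask neighbors -> ((1 + 2*0.5)/6)^3 = (1/3)^3
  m <- matrix(0L, 9, 9)
  m[6:8, 2:8] <- 1L
  w <- geometryFactor(m, c(5, 5), "protrude", g = 2, k = 3)
  expect_equal(w, (1 / 3)^3)

  # candidate completely surrounded by mask -> 1
  ring <- matrix(1L, 9, 9)
  ring[5, 5] <- 0L
  expect_equal(geometryFactor(ring, c(5, 5), "protrude"), 1)

  # empty weighted sum (no like pixels in the 8-neighborhood) -> factor 0;
  # such pixels are not valid candidates, so probe the raw stencil
  blk <- matrix(0L, 9, 9)
  blk[3:7, 3:7] <- 1L
  expect_equal(morphoRD:::cpp_geometry_factor(blk, 5L, 5L, FALSE, 2, 3), 0)
  expect_error(geometryFactor(blk, c(5, 5), "retract"), "candidate")

  # monotone in the number of like neighbors
  w1 <- geometryFactor(m, c(5, 5), "protrude")       # 3 mask nbs
  m2 <- m; m2[5, 4] <- 1L                            # 4 mask nbs
  w2 <- geometryFactor(m2, c(5, 5), "protrude")
  expect_gt(w2, w1)

  expect_error(geometryFactor(m, c(2, 2), "protrude"), "candidate")
})

test_that("volume factor has the sigmoid limits and midpoint", {
  expect_equal(volumeFactor(1000, 1000, mode = "protrude"), 0.5)
  expect_equal(volumeFactor(1000, 1000, mode = "retract"), 0.5)
  # far below reference: protrusion saturates at 1/2 + betaV
  expect_equal(volumeFactor(-1e6, 0, mode = "protrude"), 1.0)
  expect_equal(volumeFactor(1e6, 0, mode = "protrude"), 0.0)
  # V = V0 + 5000, alphaV = 1e-3: w_p = 1/(1 + e^5)
  expect_equal(volumeFactor(5000, 0, mode = "protrude"), 1 / (1 + exp(5)),
               tolerance = 1e-9)
  expect_equal(volumeFactor(5000, 0, mode = "retract"),
               1 - 1 / (1 + exp(5)), tolerance = 1e-9)
})

test_that("actin factor is neutral below threshold and biased above", {
  # betaA = 0: weak drive leaves both probabilities at 1/2
  expect_equal(actinFactor(-100, betaA = 0, mode = "protrude"), 0.5)
  expect_equal(actinFactor(-100, betaA = 0, mode = "retract"), 0.5)
  # strong drive with gammaA = 0.2: 0.7 protrude, 0.3 retract
  expect_equal(actinFactor(1e3, gammaA = 0.2, Aact = 0.1, mode = "protrude"),
               0.7)
  expect_equal(actinFactor(1e3, gammaA = 0.2, Aact = 0.1, mode = "retract"),
               0.3)
  # sigmoid midpoint: A = Aact, gammaA = 0.1 -> 0.55
  expect_equal(actinFactor(0.1, gammaA = 0.1, Aact = 0.1, mode = "protrude"),
               0.55)
})

test_that("actin extrapolation equals the masked window mean", {
  m <- matrix(0L, 8, 8)
  m[3:6, 3:6] <- 1L
  v <- matrix(0, 8, 8)
  v[3, 4] <- 0.2; v[3, 5] <- 0.4
  # candidate at (2,4)-ish: neighbors (3,3), (3,4), (3,5) in mask
  expect_equal(extrapolateActin(v, m, c(2, 4)),
               mean(c(v[3, 3], v[3, 4], v[3, 5])))

  # constant field -> the constant
  vC <- matrix(0.37, 8, 8)
  expect_equal(extrapolateActin(vC, m, c(2, 5)), 0.37)

  # random fields at random outline pixels match the brute-force oracle
  set.seed(3)
  dm <- as_int <- matrix(as.integer(maskMatrix(discMask(20, 20, 6))), 20)
  for (rep in 1:20) {
    v <- matrix(runif(400), 20, 20)
    cand <- which(dm == 0, arr.ind = TRUE)
    cand <- cand[sample(nrow(cand)), , drop = FALSE]
    for (q in seq_len(nrow(cand))) {
      r <- cand[q, 1]; c <- cand[q, 2]
      o <- window_mean_oracle(v, dm, r, c)
      if (!is.na(o)) {
        expect_equal(extrapolateActin(v, dm, c(r, c)), o)
        break
      }
    }
  }
  expect_error(extrapolateActin(v, dm, c(1, 1)), "no in-mask neighbor")
})

test_that("actin input modes return concentration or finite-difference rate", {
  a <- matrix(1:9 / 10, 3, 3)
  b <- a + 0.3
  hist <- list(list(Ga = a), list(Ga = b))
  expect_identical(actinInput(hist, "concentration", "Ga"), b)
  expect_equal(actinInput(hist, "rate", "Ga", delta = 0.05),
               matrix(0.3 / 0.05, 3, 3))
  # constant history -> zero rate
  expect_equal(actinInput(list(list(Ga = a), list(Ga = a)), "rate", "Ga"),
               matrix(0, 3, 3))
  expect_error(actinInput(list(list(Ga = a)), "rate", "Ga"), "two saved")
})

test_that("mask events respect digital topology", {
  dm <- discMask(30, 30, 8)

  # all probabilities zero: mask unchanged
  p0 <- matrix(0, 30, 30)
  expect_identical(maskMatrix(protrusionStep(dm, p0, seed = 4)$mask),
                   maskMatrix(dm))

  # all probabilities one: mask grows by a subset of the candidate ring and
  # stays a valid cell (flood-fill oracle)
  p1 <- matrix(1, 30, 30)
  res <- protrusionStep(dm, p1, seed = 4)
  expect_gt(volume(res$mask), volume(dm))
  expect_valid_mask(maskMatrix(res$mask))
  grown <- maskMatrix(res$mask) & !maskMatrix(dm)
  ring <- which(grown, arr.ind = TRUE)
  for (q in seq_len(nrow(ring))) {
    r <- ring[q, 1]; c <- ring[q, 2]
    nb <- maskMatrix(dm)[cbind(r + c(-1, 1, 0, 0), c + c(0, 0, -1, 1))]
    expect_true(any(nb))  # every added pixel was 4-adjacent to the old mask
  }

  res2 <- retractionStep(res$mask, p1, seed = 9)
  expect_valid_mask(maskMatrix(res2$mask))

  # two diagonal candidates that together would 4-disconnect the join:
  # exactly one of them is accepted
  m <- matrix(0L, 7, 9)
  m[4, 2:8] <- 1L          # horizontal bar
  hits <- integer(0)
  for (seed in 1:30) {
    pr <- matrix(0, 7, 9)
    pr[3, 4] <- 1; pr[5, 5] <- 1   # diagonal neighbors of adjacent bar pixels
    st <- protrusionStep(m, pr, seed = seed)
    hits <- c(hits, length(st$applied))
    expect_valid_mask(maskMatrix(st$mask))
  }
  expect_true(all(hits <= 2))

  # a true conflicting pair: candidates at (3,4) and (4,3)-corner around the
  # bar end cannot both commit if their union pinches the background
  m2 <- matrix(0L, 9, 9)
  m2[5, 2:5] <- 1L
  m2[4, 5] <- 1L; m2[3, 5] <- 1L   # L-shape
  pr2 <- matrix(0, 9, 9)
  pr2[4, 4] <- 1; pr2[3, 4] <- 1
  for (seed in 1:10) {
    st2 <- protrusionStep(m2, pr2, seed = seed)
    expect_valid_mask(maskMatrix(st2$mask))
  }

  # retraction floor: the mask never drops below minPixels
  small <- discMask(20, 20, 4)
  cur <- small
  for (k in 1:40) cur <- retractionStep(cur, p1[1:20, 1:20], seed = k,
                                        minPixels = 20)$mask
  expect_gte(volume(cur), 20)
  expect_valid_mask(maskMatrix(cur))
})

test_that("mass redistribution conserves totals and spreads evenly", {
  old <- matrix(0L, 10, 10)
  old[3:7, 3:7] <- 1L
  # removal: uniform value c, one pixel removed -> others at c + m/(N-1)
  newM <- old; newM[5, 7] <- 0L
  st <- list(X = matrix(0.4, 10, 10) * old)
  out <- redistributeMass(st, old, newM)
  expect_equal(sum(out$X), sum(st$X))
  expect_equal(unique(round(out$X[newM == 1L], 12)),
               round(0.4 + 0.4 / (sum(old) - 1), 12))

  # addition: total mass unchanged, spatial mean decreases
  new2 <- old; new2[2, 4:6] <- 1L
  st2 <- list(X = matrix(runif(100, 0.2, 0.8), 10, 10) * old)
  out2 <- redistributeMass(st2, old, new2)
  expect_equal(sum(out2$X), sum(st2$X), tolerance = 1e-12)
  expect_lt(mean(out2$X[new2 == 1L]), mean(st2$X[old == 1L]))
  expect_true(all(out2$X[new2 == 1L] >= 0))

  mixed <- old; mixed[3, 3] <- 0L; mixed[2, 5] <- 1L
  expect_error(redistributeMass(st, old, mixed), "nested")
})

test_that("coupled simulation keeps volume, mass and topology in check", {
  mod <- buildModel("gtpase_inhibitor")
  cfg <- solverConfig(seed = 13)
  # neutral actin regulation: volume factor pins the size near V0
  neutral <- morphoParams(gammaA = 0, betaA = 0, actinMode = "concentration")
  sim <- simulateCell(mod, neutral, cfg, discMask(60, 60, 18), nFrames = 25)
  V0 <- volume(discMask(60, 60, 18))
  expect_lt(abs(mean(sim$volume) - V0) / V0, 0.05)

  # per-component-pair total mass constant across all frames (1e-8 relative)
  for (p in list(c("Ga", "Gi"), c("Ia", "Ii"))) {
    tm <- vapply(seq_len(25), function(k)
      sum(sim$fields[[p[1]]][, , k] + sim$fields[[p[2]]][, , k]), numeric(1))
    expect_lt(diff(range(tm)) / mean(tm), 1e-8)
  }

  # no negative concentrations anywhere
  for (cc in names(sim$fields)) expect_gte(min(sim$fields[[cc]]), 0)

  # every saved mask passes the flood-fill topology oracle
  for (k in c(1, 12, 25)) expect_valid_mask(sim$masks[, , k])

  # reproducibility: same config and seed, same output
  sim2 <- simulateCell(mod, neutral, cfg, discMask(60, 60, 18), nFrames = 3)
  sim3 <- simulateCell(mod, neutral, cfg, discMask(60, 60, 18), nFrames = 3)
  expect_identical(sim2$masks, sim3$masks)
  expect_identical(sim2$fields, sim3$fields)
})

test_that("edge-threshold dynamics confine activity to the mask boundary", {
  mod <- buildModel("gtpase_inhibitor")
  mp <- actinPreset("gtpase_inhibitor", "rate")
  sim <- simulateCell(mod, mp, solverConfig(seed = 2), discMask(80, 80, 28),
                      nFrames = 40, burnIn = 20)
  # pixels with clearly elevated activity should hug the outline (within 3 px)
  hits <- 0L; near <- 0L
  for (k in seq(5, 40, 5)) {
    m <- sim$masks[, , k] == 1
    ga <- sim$fields$Ga[, , k]
    thr <- ga > 0.5   # half the total GTPase concentration

    if (!any(thr & m)) next
    bp <- boundary_pixels(m)
    dist <- bp
    for (d in 1:2) dist <- dist | EBImage::imageData(EBImage::dilate(
      EBImage::Image(dist * 1), EBImage::makeBrush(3, "box"))) > 0
    hits <- hits + sum(thr & m)
    near <- near + sum(thr & m & dist)
  }
  expect_gt(hits, 0)
  expect_gte(near / hits, 0.9)
})
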