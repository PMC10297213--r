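# Biosensor normalization, contour machinery, trajectory tracking,
# kymographs, peak-aligned analysis and unit calibration.

make_disc_stack <- function(radii, size = 64) {
  nf <- length(radii)
  arr <- array(FALSE, c(size, size, nf))
  for (k in seq_len(nf))
    arr[, , k] <- maskMatrix(discMask(size, size, radii[k]))
  arr
}

test_that("biosensor normalization clips at 6 MAD and scales to [0, 1]", {
  set.seed(8)
  st <- array(rnorm(10 * 10 * 3, 5, 1), c(10, 10, 3))
  out <- normalizeBiosensor(st)
  expect_equal(min(out), 0)
  expect_equal(max(out), 1)
  expect_true(all(out >= 0 & out <= 1))

  # a single extreme pixel is clipped to median + 6 MAD before scaling:
  # it maps to 1 but the dynamic range of the rest is preserved
  st2 <- st
  st2[5, 5, 2] <- 1e6
  out2 <- normalizeBiosensor(st2)
  expect_equal(out2[5, 5, 2], 1)
  med <- median(st2); madI <- mad(st2, constant = 1)
  clipped <- pmin(pmax(st2, med - 6 * madI), med + 6 * madI)
  expected <- (clipped - min(clipped)) / (max(clipped) - min(clipped))
  expect_equal(out2[, , 1], expected[, , 1], tolerance = 1e-12)
  # an un-clipped stack keeps its ordering
  expect_true(cor(as.vector(out), as.vector(st)) > 0.99)

  expect_warning(n0 <- normalizeBiosensor(array(3, c(4, 4, 2))), "constant")
  expect_true(all(n0 == 0))
})

test_that("windowed contours bound the union and intersection", {
  # static disc: outer == inner == mask boundary
  st <- make_disc_stack(rep(20, 20))
  cs <- windowContours(st, window = 20)
  expect_length(cs, 1)
  ctr <- c(32.5, 32.5)
  ro <- sqrt(rowSums(sweep(cs[[1]]@outer, 2, ctr)^2))
  ri <- sqrt(rowSums(sweep(cs[[1]]@inner, 2, ctr)^2))
  expect_lt(abs(mean(ro) - mean(ri)), 0.3)

  # disc oscillating between radius 15 and 21
  radii <- 18 + 3 * sin(2 * pi * (1:20) / 10)
  st2 <- make_disc_stack(radii)
  cs2 <- windowContours(st2, window = 20)
  ro2 <- sqrt(rowSums(sweep(cs2[[1]]@outer, 2, ctr)^2))
  ri2 <- sqrt(rowSums(sweep(cs2[[1]]@inner, 2, ctr)^2))
  expect_lt(abs(mean(ro2) - max(radii)), 1)
  expect_lt(abs(mean(ri2) - min(radii)), 1)

  # resampling contract: consecutive spacing within [0.5, 1.5] px
  seg <- sqrt(rowSums((cs2[[1]]@outer -
                         cs2[[1]]@outer[c(2:nrow(cs2[[1]]@outer), 1), ])^2))
  expect_true(all(seg >= 0.5 & seg <= 1.5))

  # mid-contour lies between the two
  rm_ <- sqrt(rowSums(sweep(cs2[[1]]@mid, 2, ctr)^2))
  expect_true(all(rm_ < max(ro2) + 0.5 & rm_ > min(ri2) - 0.5))
})

test_that("mid-contour of an annulus converges to the central circle", {
  outer <- circle_contour(20)
  inner <- circle_contour(10)
  mid <- midContour(outer, inner, tol = 0.1)
  r <- sqrt(rowSums(sweep(mid, 2, c(32, 32))^2))
  expect_lt(max(abs(r - 15)), 0.2)
  expect_lt(attr(mid, "finalDistance"), 0.1)
  expect_gte(attr(mid, "iterations"), 1)

  # identical contours come back immediately
  same <- midContour(outer, outer)
  expect_identical(attr(same, "iterations"), 0L)

  # eccentric annulus still converges below tolerance
  inner2 <- circle_contour(8, center = c(35, 30))
  mid2 <- midContour(outer, inner2, tol = 0.1)
  expect_lt(attr(mid2, "finalDistance"), 0.1)
})

test_that("trajectories track static and uniformly expanding discs", {
  # static disc: fixed points, zero velocity
  st <- make_disc_stack(rep(18, 20))
  cs <- windowContours(st)
  b <- buildTrajectories(cs, st)
  expect_lt(max(abs(b@velocity), na.rm = TRUE), 0.25)

  # trajectory count ~ mid-contour perimeter in px (1-px resampling)
  per <- nrow(cs[[1]]@mid)
  expect_lt(abs(nrow(b@x) - per) / per, 0.1)

  # expanding disc at 1 px/frame: velocities ~ +1 (protrusion positive)
  st2 <- make_disc_stack(10 + (1:20))
  cs2 <- windowContours(st2)
  b2 <- buildTrajectories(cs2, st2)
  v <- b2@velocity[, 2:20]
  expect_lt(abs(mean(v, na.rm = TRUE) - 1), 0.1)

  # 90-degree rotation leaves the velocity statistics unchanged
  str_ <- array(FALSE, dim(st2))
  for (k in 1:20) str_[, , k] <- t(st2[, , k])[, ]
  b2r <- buildTrajectories(windowContours(str_), str_)
  expect_lt(abs(mean(b2r@velocity[, 2:20], na.rm = TRUE) -
                  mean(v, na.rm = TRUE)), 0.05)
})

test_that("kymographs sample velocity and in-mask disc signal", {
  st <- make_disc_stack(rep(16, 20))
  sig <- array(0.42, c(64, 64, 20))
  cs <- windowContours(st)
  b <- buildTrajectories(cs, st)
  kk <- kymographs(b, sig, st, radius = 2)
  expect_equal(max(abs(kk$velocity@data), na.rm = TRUE), 0,
               tolerance = 0.25)
  expect_equal(unique(round(kk$signal@data[!is.na(kk$signal@data)], 10)),
               0.42)

  # signal sampling equals the brute-force masked disc mean
  set.seed(5)
  img <- matrix(runif(64 * 64), 64, 64)
  msk <- st[, , 1]
  for (q in 1:25) {
    x <- runif(1, 18, 46); y <- runif(1, 18, 46)
    got <- morphoRD:::sampleDiscMean(img, msk, x, y, 2)
    want <- disc_mean_oracle(img, msk, x, y, 2)
    expect_equal(got, want)
  }
})

test_that("peak alignment recovers injected signal-velocity lags", {
  set.seed(17)
  nt <- 60L; nf <- 140L
  for (L in c(0L, 3L, 8L)) {
    # per-trajectory pulse train: signal is the velocity shifted by L frames
    V <- matrix(0, nt, nf)
    for (i in seq_len(nt)) {
      ph <- runif(1, 0, 2 * pi)
      V[i, ] <- pmax(sin(2 * pi * (1:nf) / 35 + ph), 0)^2 +
        rnorm(nf, 0, 0.03)
    }
    S <- cbind(matrix(0, nt, L), V)[, seq_len(nf), drop = FALSE]
    vk <- new("Kymograph", data = V, kind = "velocity",
              peaks = data.frame(trajectory = integer(0), frame = integer(0)))
    sk <- new("Kymograph", data = S, kind = "signal",
              peaks = data.frame(trajectory = integer(0), frame = integer(0)))
    for (rule in c("as-printed", "plus")) {
      ps <- peakAlignedAnalysis(vk, sk, peakRule = rule)
      expect_gt(ps@nPeaks, 10)
      expect_lte(abs(peakLag(ps) - L), 1)
      # coordinate trace is exactly the cumulative sum of the velocity trace
      expect_equal(ps@coordinate, cumsum(ps@velocity))
      # aligned velocity peaks at the center frame
      expect_equal(which.max(ps@velocity), 21L)
    }
  }
})

test_that("region size filter keeps 15-px ridges and drops 5-px ridges", {
  nt <- 40L; nf <- 120L
  V <- matrix(0, nt, nf)
  # long ridge on trajectory 10 (15 frames), short on trajectory 30 (5)
  V[10, 41:55] <- 1 + sin((1:15) / 15 * pi)
  V[30, 61:65] <- 2 + sin((1:5) / 5 * pi)
  vk <- new("Kymograph", data = V, kind = "velocity",
            peaks = data.frame(trajectory = integer(0), frame = integer(0)))
  sk <- new("Kymograph", data = V, kind = "signal",
            peaks = data.frame(trajectory = integer(0), frame = integer(0)))
  ps <- peakAlignedAnalysis(vk, sk, peakRule = "plus")
  expect_identical(ps@nPeaks, 1L)       # only the long ridge's maximum
  expect_equal(which.max(ps@velocity), 21L)
  # and the ridge is on trajectory 10 around frame 48
  expect_gt(ps@velocity[21], 1.5)
})

test_that("trajectory outlier filter drops 20-SD artifacts", {
  set.seed(30)
  nt <- 30L; nf <- 100L
  V <- matrix(rnorm(nt * nf, 0, 0.1), nt, nf)
  V[7, ] <- V[7, ] + c(rep(0, 49), 500, rep(0, 50))  # segmentation artifact
  S <- V
  vk <- new("Kymograph", data = V, kind = "velocity",
            peaks = data.frame(trajectory = integer(0), frame = integer(0)))
  sk <- new("Kymograph", data = S, kind = "signal",
            peaks = data.frame(trajectory = integer(0), frame = integer(0)))
  ps <- suppressWarnings(peakAlignedAnalysis(vk, sk))
  # the artifact peak (by far the global maximum) must not survive
  expect_lt(max(ps@velocity, na.rm = TRUE), 400)
})

test_that("unit calibration matches decorrelation scales", {
  # white noise: temporal autocorrelation ~ 0 at lag >= 1
  set.seed(2)
  W <- matrix(rnorm(50 * 200), 50, 200)
  acfT <- morphoRD:::kymAutocorrelation(W, "time", maxLag = 10)
  expect_lt(max(abs(acfT[-1])), 0.05)

  # sinusoidal velocity of period T: first autocorrelation zero ~ T/4
  Tper <- 24
  S <- matrix(rep(sin(2 * pi * (1:240) / Tper), each = 40), 40, 240)
  S <- S + matrix(rnorm(40 * 240, 0, 0.01), 40, 240)
  acfS <- morphoRD:::kymAutocorrelation(S, "time", maxLag = 40)
  firstZero <- which(acfS < 0)[1] - 1
  expect_lte(abs(firstZero - Tper / 4), 1)

  # identical sim and experimental kymographs: conversion factors 1
  cal <- calibrateUnits(S, S)
  expect_equal(cal$secondsPerAU, 1, tolerance = 1e-8)
  expect_equal(cal$micronsPerAU, 1, tolerance = 1e-8)

  # stored constants when no experimental input is given
  def <- calibrateUnits(S)
  expect_equal(def$secondsPerAU, 0.65)
  expect_equal(def$micronsPerAU, 10.127)

  expect_error(calibrateUnits(matrix(1, 10, 10) + 0 * S[1:10, 1:10],
                              matrix(1, 10, 10)), "flat|empty")
})
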