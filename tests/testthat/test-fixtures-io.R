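# Synthetic ruffling fixtures, end-to-end lag recovery, file round-trips and
# deterministic outputs.

test_that("ruffling fixture honors its specification", {
  # zero amplitude: static disc, zero velocity everywhere
  fx0 <- makeRufflingStack(size = 64, baseRadius = 18, amplitude = 0,
                           nFrames = 30, noiseSD = 0, seed = 5)
  expect_true(all(fx0$masks[, , 1] == fx0$masks[, , 30]))
  b <- buildTrajectories(windowContours(fx0$masks), fx0$masks)
  expect_lt(max(abs(b@velocity), na.rm = TRUE), 0.3)

  # invariants on the generator inputs
  expect_error(makeRufflingStack(size = 50, baseRadius = 24, amplitude = 6),
               "half the frame")
  expect_error(makeRufflingStack(period = 3), "period")

  # masks are valid simply connected cells at every frame
  fx <- makeRufflingStack(size = 80, baseRadius = 24, amplitude = 5,
                          period = 24, nFrames = 24, seed = 2)
  for (k in c(1, 8, 16, 24)) expect_valid_mask(fx$masks[, , k])

  # ground-truth table reflects the requested lags
  fx2 <- makeRufflingStack(lags = c(-2, 0, 5), nFrames = 12, seed = 1)
  expect_equal(fx2$truth$lag, c(-2, 0, 5))
  expect_length(fx2$signals, 3)
})

test_that("pipeline recovers injected lags end to end", {
  # the central validation: masks + delayed-signal stacks in, lag out
  for (seed in c(11, 12)) {
    fx <- makeRufflingStack(size = 90, baseRadius = 26, amplitude = 6,
                            period = 48, lags = c(0, 5), nFrames = 120,
                            seed = seed)
    for (k in 1:2) {
      res <- analyzeStack(fx$masks, fx$signals[[k]])
      expect_lte(abs(peakLag(res$summary) - fx$truth$lag[k]), 1)
    }
  }
})

test_that("protrusion phases of the fixture yield positive mean velocity", {
  fx <- makeRufflingStack(size = 80, baseRadius = 24, amplitude = 6,
                          period = 40, nFrames = 80, seed = 9, noiseSD = 0)
  b <- buildTrajectories(windowContours(fx$masks), fx$masks)
  # frames where the lobes protrude: identify from the mask area increase
  area <- apply(fx$masks, 3, sum)
  growing <- which(diff(area) > 0) + 1L
  expect_gt(mean(b@velocity[, growing], na.rm = TRUE), 0)
})

test_that("TIFF and CSV round-trips preserve stacks and kymographs", {
  dir <- withr::local_tempdir()
  fx <- makeRufflingStack(size = 48, baseRadius = 14, amplitude = 3,
                          nFrames = 4, seed = 3)
  fm <- file.path(dir, "m.tif")
  writeStackTiff(fx$masks, fm)
  rt <- readStackTiff(fm)
  expect_equal(dim(rt), dim(fx$masks))
  expect_true(all((rt > 0.5) == (fx$masks > 0)))

  fs <- file.path(dir, "s.tif")
  writeStackTiff(fx$signals[[1]], fs)
  rs <- readStackTiff(fs)
  expect_equal(as.numeric(rs), as.numeric(fx$signals[[1]]), tolerance = 1e-6)

  K <- new("Kymograph", data = matrix(rnorm(20), 4, 5), kind = "velocity",
           peaks = data.frame(trajectory = integer(0), frame = integer(0)))
  fk <- file.path(dir, "k.csv")
  writeKymographCsv(K, fk)
  back <- read.csv(fk)
  expect_equal(as.matrix(back[, -1]), kymMatrix(K), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("configs round-trip through YAML and runs are deterministic", {
  dir <- withr::local_tempdir()
  cfg <- list(model = "gtpase_inhibitor", actinMode = "rate", grid = 60L,
              radius = 18, nFrames = 4L, seed = 7L, saveEvery = 500L)
  fy <- file.path(dir, "cfg.yaml")
  writeConfig(cfg, fy)
  expect_identical(readConfig(fy)[names(cfg)], cfg)

  # identical config + seed -> byte-identical CSV outputs
  d1 <- file.path(dir, "r1"); d2 <- file.path(dir, "r2")
  r1 <- suppressWarnings(runExperiment(fy, outDir = d1))
  r2 <- suppressWarnings(runExperiment(fy, outDir = d2))
  f1 <- file.path(d1, "kymograph_velocity.csv")
  f2 <- file.path(d2, "kymograph_velocity.csv")
  expect_true(file.exists(f1))
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(r1$sim$volume, r2$sim$volume)

  # the emitted effective config re-runs to the same result (round trip)
  r3 <- suppressWarnings(runExperiment(file.path(d1, "config.yaml")))
  expect_identical(r3$sim$volume, r1$sim$volume)
})

test_that("the command-line front end lists models and builds fixtures", {
  script <- system.file("scripts", "morphoRD", package = "morphoRD")
  expect_true(nzchar(script))
  out <- system2("Rscript", c(script, "list-models"), stdout = TRUE)
  expect_true(any(grepl("gtpase_inhibitor", out)))
  dir <- withr::local_tempdir()
  out2 <- system2("Rscript", c(script, "fixtures", "--out", dir,
                               "--lags", "0,3", "--frames", "8",
                               "--seed", "2"), stdout = TRUE)
  expect_true(file.exists(file.path(dir, "masks.tif")))
  expect_true(file.exists(file.path(dir, "signal_ch2.tif")))
  truth <- read.csv(file.path(dir, "truth.csv"))
  expect_equal(truth$lag, c(0, 3))
})

test_that("simulation export writes stacks, volume and metadata", {
  dir <- withr::local_tempdir()
  mod <- buildModel("mcrd_single")
  sim <- simulateCell(mod, morphoParams(gammaA = 0, actinMode = "concentration"),
                      solverConfig(seed = 3, saveEvery = 200L),
                      discMask(40, 40, 12), nFrames = 3)
  writeSimulation(sim, dir)
  expect_true(file.exists(file.path(dir, "mask.tif")))
  expect_true(file.exists(file.path(dir, "Ga.tif")))
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"))
  expect_equal(meta$model, "mcrd_single")
  expect_equal(meta$nFrames, 3)
  vol <- read.csv(file.path(dir, "volume.csv"))
  expect_equal(vol$volume, sim$volume)
})
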