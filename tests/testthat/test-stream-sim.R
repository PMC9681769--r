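test_that("droplet trains are bitwise reproducible for a fixed seed", {
  cfg <- simConfig(sessionLength = 60, seed = 11)
  a <- simulateDropletTrain(cfg)
  b <- simulateDropletTrain(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  fa <- synthesizeFrames(a[1:20, ], detectorModel(), tRange = c(0, 3), seed = 5)
  fb <- synthesizeFrames(b[1:20, ], detectorModel(), tRange = c(0, 3), seed = 5)
  expect_identical(intensityMatrix(fa), intensityMatrix(fb))
})

test_that("occupancy follows the configured Poisson law", {
  # lambda = 0: every droplet empty
  tr0 <- simulateDropletTrain(simConfig(sessionLength = 30,
                                        occupancyLambda = 0, seed = 2))
  expect_true(all(tr0$n_spores == 0))
  # spore concentration 0.35e6 /mL in 1 nL droplets gives lambda 0.35
  cfg <- simConfig(sporeConcentration = 0.35e6, dropletVolumeMean = 1,
                   sessionLength = 10)
  expect_equal(cfg@occupancyLambda, 0.35)
  # chi-square goodness of fit over >= 10,000 droplets, alpha = 0.001
  tr <- simulateDropletTrain(simConfig(sessionLength = 2000, seed = 3))
  expect_gte(nrow(tr), 10000)
  ks <- table(factor(pmin(tr$n_spores, 3), levels = 0:3))
  p <- c(dpois(0:2, 0.35), ppois(2, 0.35, lower.tail = FALSE))
  gof <- suppressWarnings(chisq.test(as.integer(ks), p = p))
  expect_gt(gof$p.value, 0.001)
})

test_that("arrival processes keep the configured mean rate", {
  for (mode in c("dead_time", "poisson", "regular")) {
    tr <- simulateDropletTrain(simConfig(sessionLength = 1800, seed = 4,
                                         arrivalMode = mode))
    gaps <- diff(tr$arrival_time)
    se <- sd(gaps) / sqrt(length(gaps))
    expect_lt(abs(mean(gaps) - 1 / 7), max(3 * se, 1e-12))
    expect_false(is.unsorted(tr$arrival_time))
  }
  # dead-time trains never overlap transits
  tr <- simulateDropletTrain(simConfig(sessionLength = 600, seed = 5))
  expect_gte(min(diff(tr$arrival_time)), 0.1 - 1e-12)
  expect_error(simConfig(dropletRate = -1), "dropletRate")
  expect_error(simConfig(sessionLength = 0), "sessionLength")
})

test_that("fluorescein accumulation is linear, saturating and monotone", {
  cfg <- simConfig(incubationTime = 48, backgroundUM = 0.5)
  # hand-evaluated linear model: 0.5 + 1 * 48
  expect_equal(incubationFluorescence(1, cfg), 48.5)
  # ceiling at the substrate concentration
  cfg96 <- simConfig(incubationTime = 96, backgroundUM = 0.5)
  expect_equal(incubationFluorescence(10, cfg96), 100)
  # empty droplet: background only
  expect_equal(incubationFluorescence(0, cfg), 0.5)
  expect_error(incubationFluorescence(1, simConfig(incubationTime = 0)),
               NA)
  expect_error(simConfig(incubationTime = -1), "incubationTime")
  # non-decreasing in incubation time, never above the ceiling
  rates <- c(0, 0.3, 1, 5, 20)
  prev <- rep(-Inf, length(rates))
  for (t in c(0, 6, 12, 24, 48, 96, 200)) {
    conc <- incubationFluorescence(rates, simConfig(incubationTime = max(t, 1e-9)))
    expect_true(all(conc >= prev))
    expect_true(all(conc <= 100))
    prev <- conc
  }
})

test_that("hyphal exit respects media-dependent onsets", {
  expect_error(simConfig(media = "PDB"), "media")
  # empty droplets never exit
  cfg <- simConfig(sessionLength = 300, media = "G1", seed = 6)
  tr <- simulateDropletTrain(cfg)
  expect_true(all(is.na(tr$hyphal_exit_time[tr$n_spores == 0])))
  occ <- tr$hyphal_exit_time[tr$n_spores > 0]
  expect_true(all(!is.na(occ)))
  # glucose media: no exits strictly before 24 h
  expect_gte(min(occ), 24)
  # colloidal chitin + low glucose: exit fraction still zero at 95 h
  tr2 <- simulateDropletTrain(simConfig(sessionLength = 300,
                                        media = "CC1_G01", seed = 7))
  expect_equal(sum(tr2$hyphal_exit_time <= 95, na.rm = TRUE), 0)
})

test_that("synthesized streams carry transits where and when expected", {
  det <- detectorModel()
  # empty train: frames are baseline + noise only
  empty <- make_train(0, arrival_time = numeric(0))
  fr <- synthesizeFrames(empty, det, tRange = c(0, 1), seed = 8)
  resid <- sweep(intensityMatrix(fr), 1, det@darkSpectrum)
  expect_lt(max(abs(resid)), 6 * det@noiseSD)
  # one droplet at 50 uM: in-transit frames peak at 515 +- one grid step
  # (argmax on the noise-free construction)
  det0 <- detectorModel(noiseSD = 0)
  tr <- make_train(1, arrival_time = 0.5, fluorescein_conc = 50)
  fr <- synthesizeFrames(tr, det0, tRange = c(0, 1), seed = 9)
  mat <- intensityMatrix(fr)
  hot <- which(frameTimes(fr) >= 0.5 & frameTimes(fr) <= 0.54)
  expect_gt(length(hot), 0)
  for (j in hot) {
    wl_max <- wavelengths(fr)[which.max(mat[, j] - det0@darkSpectrum)]
    expect_lte(abs(wl_max - 515), 0.5)
  }
  # unsorted trains are rejected by the class invariant
  expect_error(make_train(2, arrival_time = c(1, 0.5)), "non-decreasing")
})

test_that("mutant libraries are right-skewed relative to the parent strain", {
  parent <- simulateDropletTrain(simConfig(sessionLength = 400,
                                           mutantFraction = 0, seed = 10))
  mutant <- simulateDropletTrain(simConfig(sessionLength = 400,
                                           mutantFraction = 0.3, seed = 10))
  cmp <- comparePopulations(parent$fluorescein_conc[parent$n_spores > 0],
                            mutant$fluorescein_conc[mutant$n_spores > 0])
  expect_gt(cmp$skewness_mutant, cmp$skewness_parent)
})
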