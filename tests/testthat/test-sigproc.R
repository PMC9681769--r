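test_that("background subtraction implements both printed modes", {
  # accumulate recurrence, element-wise, hand-evaluated
  expect_equal(subtractBackground(100, 40, previous = 0, mode = "accumulate"), 60)
  expect_equal(subtractBackground(90, 40, previous = 60, mode = "accumulate"), 110)
  # plain mode: identical spectra cancel exactly
  dark <- runif(11, 40, 60)
  expect_equal(subtractBackground(dark, dark), rep(0, 11))
  # output is non-negative in both modes
  x <- c(10, 50, 30); d <- c(40, 40, 40)
  expect_true(all(subtractBackground(x, d) >= 0))
  expect_true(all(subtractBackground(x, d, previous = c(0, 0, 0),
                                     mode = "accumulate") >= 0))
  expect_error(subtractBackground(1:5, 1:4), "grids")
  expect_error(subtractBackground(1:5, 1:5, mode = "accumulate"), "previous")
})

test_that("Butterworth denoising matches its analytic magnitude response", {
  # DC gain 1: long constant signal unchanged at steady state
  y <- denoiseSpectrum(rep(3.7, 600), filterSettings())
  expect_lt(max(abs(y[500:600] - 3.7)), 3.7 * 1e-6)
  # steady-state amplitude ratios at fc and 4 fc equal the analytic
  # magnitude of the digital (bilinear) filter: 1/sqrt(2) at the cutoff by
  # prewarping, and the warped value at 4 fc
  expect_equal(filtered_amplitude(0.1), 1 / sqrt(2), tolerance = 1e-3)
  expect_equal(filtered_amplitude(0.4), digital_butter_gain(0.4),
               tolerance = 5e-3)
  expect_equal(digital_butter_gain(0.1), 1 / sqrt(2), tolerance = 1e-12)
  expect_error(denoiseSpectrum(1:5, filterSettings(order = 3)), "short")
  expect_error(filterSettings(cutoff = 1.5), "cutoff")
})

test_that("peak detection enforces all four criteria", {
  wl <- seq(450, 650, by = 0.5)
  # flat spectrum: nothing
  expect_equal(nrow(detectPeaks(rep(5, length(wl)), wl)), 0)
  # single Gaussian bump: exactly one peak at its centre and amplitude
  sp <- gaussian_spectrum(515, 1000, sd = 10)
  pk <- detectPeaks(sp$y, sp$wl, peakCriteria(minHeight = 100))
  expect_equal(nrow(pk), 1)
  expect_lte(abs(pk$wavelength - 515), 0.5)
  expect_equal(pk$intensity, 1000, tolerance = 1e-6)
  # two Gaussians separated by 55 nm with min distance 10 nm: both kept
  two <- gaussian_spectrum(505, 800, sd = 6)
  two$y <- two$y + gaussian_spectrum(560, 600, sd = 6)$y
  pk2 <- detectPeaks(two$y, two$wl,
                     peakCriteria(minHeight = 100, minDistance = 10))
  expect_equal(sort(round(pk2$wavelength)), c(505, 560))
  # ... but a 5 nm separation rule keeps only the taller of two 4 nm-apart peaks
  close2 <- gaussian_spectrum(513, 800, sd = 1.5)
  close2$y <- close2$y + gaussian_spectrum(517, 600, sd = 1.5)$y
  pk3 <- detectPeaks(close2$y, close2$wl,
                     peakCriteria(minHeight = 100, minDistance = 5))
  expect_equal(nrow(pk3), 1)
  expect_lte(abs(pk3$wavelength - 513), 1)
  # every reported peak satisfies the criteria; prominence <= height
  set.seed(40)
  for (i in 1:20) {
    y <- abs(rnorm(length(wl), sd = 30)) +
      gaussian_spectrum(sample(480:620, 1), runif(1, 100, 2000), sd = 8)$y
    crit <- peakCriteria(minHeight = 60, minBaseWidth = 1.5,
                         minDistance = 8, minProminence = 40)
    pk <- detectPeaks(y, wl, crit)
    if (nrow(pk)) {
      expect_true(all(pk$intensity >= crit@minHeight))
      expect_true(all(pk$prominence >= crit@minProminence))
      expect_true(all(pk$base_width >= crit@minBaseWidth))
      expect_true(all(pk$prominence <= pk$intensity))
      if (nrow(pk) > 1) {
        expect_true(all(diff(pk$wavelength) >= crit@minDistance))
        expect_false(is.unsorted(pk$wavelength))
      }
    }
  }
})

test_that("event segmentation merges frames within the refractory interval", {
  # 4 consecutive hot frames, 10 ms apart, 50 ms refractory: one event
  ev <- segmentEvents(make_peaks(c(0.10, 0.11, 0.12, 0.13)), refractory = 0.05)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_frames, 4L)
  # two transits 143 ms apart (7 Hz): two events
  ev2 <- segmentEvents(make_peaks(c(0.10, 0.11, 0.243, 0.253)),
                       refractory = 0.05)
  expect_equal(nrow(ev2), 2)
  # event peak is the maximum-intensity frame peak
  p <- make_peaks(c(0.1, 0.11, 0.12), intensity = c(500, 900, 700))
  ev3 <- segmentEvents(p, refractory = 0.05)
  expect_equal(ev3$intensity, 900)
  expect_equal(ev3$peak_time, 0.11)
  # no hot frames: empty table
  expect_equal(nrow(segmentEvents(make_peaks(numeric(0)))), 0)
  expect_error(segmentEvents(make_peaks(c(0.2, 0.1))), "ordered")
})

test_that("gating is a pure idempotent flag with closed windows", {
  g <- gate(wavelengthMin = 510, wavelengthMax = 520, intensityMin = 100,
            noiseLevel = 50)
  ev <- make_events(c(1, 2, 3, 4), wavelength = c(515, 509.9, 515, 520),
                    intensity = c(500, 500, 60, 100))
  out <- applyGate(ev, g)
  # in-window peak gated; 509.9 nm violates the closed 510 nm edge;
  # below-intensity-floor not gated; boundary intensity (closed) gated
  expect_equal(out$gated, c(TRUE, FALSE, FALSE, TRUE))
  expect_identical(applyGate(out, g), out)
  expect_equal(nrow(applyGate(ev[0, ], g)), 0)
  expect_error(gate(intensityMin = 10, noiseLevel = 20), "noiseLevel")
})

test_that("quantile gates pass the intended population tail", {
  # linear-interpolation quantile by hand: 0.9 of 1..10 is 9.1
  g <- quantileGate(1:10, 0.9)
  expect_equal(g@intensityMin, 9.1)
  # all values equal: threshold is that value, nothing strictly above
  g2 <- quantileGate(rep(7, 50), 0.9)
  expect_equal(g2@intensityMin, 7)
  expect_equal(mean(rep(7, 50) > g2@intensityMin), 0)
  # continuous draws: ~10% above the 0.9-quantile threshold
  set.seed(41)
  x <- rlnorm(10000, 5, 0.6)
  g3 <- quantileGate(x, 0.9)
  expect_equal(mean(x > g3@intensityMin), 0.1, tolerance = 0.1)
  expect_error(quantileGate(5, 0.9), "at least 2")
  expect_error(quantileGate(1:10, 1.2), "q must be")
})

test_that("peak histograms conserve counts and expose gate-setting summaries", {
  ev <- make_events(seq(0.1, by = 0.2, length.out = 500),
                    intensity = rlnorm(500, 6, 0.4))
  h <- peakHistogram(ev, breaks = 40)
  expect_equal(sum(h$counts), 500)
  expect_equal(h$n, 500)
  expect_named(h$quantiles)
  h1 <- peakHistogram(make_events(0.1, intensity = 123))
  expect_equal(sum(h1$counts > 0), 1)
  expect_error(peakHistogram(make_events(numeric(0))), "no events")
})

test_that("the frame chain recovers isolated transits and stays within the gate window", {
  det <- detectorModel()
  tr <- make_train(6, arrival_time = seq(0.5, by = 0.5, length.out = 6),
                   fluorescein_conc = c(5, 10, 20, 40, 8, 50))
  fr <- synthesizeFrames(tr, det, tRange = c(0, 3.6), seed = 12)
  pk <- processFrames(fr, dark = det@darkSpectrum)
  ev <- segmentEvents(pk)
  expect_equal(nrow(ev), 6)
  # causal filtering shifts peaks by the group delay; they must stay
  # inside the 510-520 nm gating window
  expect_true(all(ev$wavelength >= 510 & ev$wavelength <= 520))
  # intensities track concentration ordering
  expect_equal(order(ev$intensity), order(tr$fluorescein_conc))
})
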