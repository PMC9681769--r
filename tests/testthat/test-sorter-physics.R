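test_that("default coefficients reproduce the calibration anchors", {
  m <- dropletRoutingModel()
  # P = 0.5 inflection at (27.4 V_RMS, 51.5 nL/s, 1 nL)
  expect_equal(actuatedSuccessProb(27.4, 51.5, 1, m), 0.5, tolerance = 1e-12)
  # efficient screening regime
  expect_gt(actuatedSuccessProb(40, 60, 1, m), 0.9)
  # polydisperse regime: > 0.5 success for volumes below ~1 nL
  expect_gt(actuatedSuccessProb(36.34, 60, 0.8, m), 0.5)
  # shipped YAML equals the documented calibration
  cal <- calibrateRoutingModel()
  for (s in c("beta0", "betaV", "betaQ", "betaVQ", "betaVol"))
    expect_equal(slot(m, s), slot(cal, s), tolerance = 1e-12)
})

test_that("actuated success is monotone in V and favours small droplets", {
  m <- dropletRoutingModel()
  for (q in c(5, 20, 51.5, 60, 80, 100)) {
    p <- actuatedSuccessProb(seq(4.6, 51.8, by = 0.4), q, 1, m)
    expect_true(all(diff(p) > 0))
  }
  # volume -> 0 limit beats volume 1 when the volume coefficient is negative
  expect_gt(actuatedSuccessProb(36.34, 60, 1e-9, m),
            actuatedSuccessProb(36.34, 60, 1, m))
  expect_error(actuatedSuccessProb(-1, 50), ">= 0")
})

test_that("passive routing fidelity matches its flow anchors", {
  m <- dropletRoutingModel()
  expect_equal(passiveFidelity(80, m), 0.995)
  expect_equal(passiveFidelity(60, m), 0.992)
  expect_equal(passiveFidelity(70, m), (0.995 + 0.992) / 2)
  # low-flow inversion: fidelity collapses below 10 nL/s
  expect_lt(passiveFidelity(5, m), 0.992)
  # empirical false-positive rate equals 1 - fidelity within binomial error
  routed <- routeDroplets(10000, pulsed = FALSE, V = 0, Q = 60, seed = 18)
  fp <- mean(routed$routed_channel == "disfavored")
  expect_lt(abs(fp - 0.008), 4 * sqrt(0.008 * 0.992 / 10000))
})

test_that("failure modes follow the regime classification", {
  m <- dropletRoutingModel()
  # low potential, high flow: failures are E1 and escape into main
  r1 <- routeDroplets(2000, pulsed = TRUE, V = 10, Q = 90, seed = 19)
  f1 <- r1[r1$failure_mode != "none", ]
  expect_gt(nrow(f1), 0)
  expect_true(all(f1$failure_mode == "E1"))
  expect_true(all(f1$routed_channel == "main"))
  # low flow with the pulse still active at the next arrival: E3 merges
  r3 <- routeDroplets(2000, pulsed = TRUE, V = 45, Q = 20,
                      nextGap = rep(0.1, 2000), seed = 20)
  f3 <- r3[r3$failure_mode != "none", ]
  expect_gt(nrow(f3), 0)
  expect_true(all(f3$failure_mode == "E3"))
  expect_true(all(f3$routed_channel == "merged"))
  # same regime with long gaps: E2 stalls
  r2 <- routeDroplets(2000, pulsed = TRUE, V = 45, Q = 20, seed = 20)
  f2 <- r2[r2$failure_mode != "none", ]
  expect_true(all(f2$failure_mode == "E2"))
  # channel assignment is exhaustive and exclusive
  expect_true(all(r1$routed_channel %in% c("main", "disfavored", "merged")))
  expect_equal(nrow(r1), 2000)
})

test_that("the efficiency grid has the characterization shape", {
  g <- efficiencyGrid(seed = 21)
  expect_equal(nrow(g), 140)
  expect_equal(length(unique(g$v_rms)), 7)
  expect_equal(length(unique(g$q_nl_s)), 20)
  expect_true(all(g$successes >= 0 & g$successes <= 10))
  expect_true(all(g$n == 10))
  # saturated logistic: intercept-only +Inf model sorts every droplet
  sat <- new("RoutingModel", beta0 = Inf, betaV = 0, betaQ = 0, betaVQ = 0,
             betaVol = 0, passiveFidelity80 = 0.995,
             passiveFidelity60 = 0.992, vLow = 27.4, qLow = 51.5)
  gs <- efficiencyGrid(N = 10, model = sat, seed = 22)
  expect_true(all(gs$successes == 10))
  # Monte Carlo at the anchor cell converges to 0.5
  ga <- efficiencyGrid(vLevels = 27.4, qLevels = 51.5, N = 10000, seed = 23)
  expect_equal(ga$successes / ga$n, 0.5, tolerance = 0.03)
  expect_error(efficiencyGrid(N = 0), "N must be")
})

test_that("grid refits recover the generating coefficients within 3 SE", {
  m <- dropletRoutingModel()
  truth <- c(m@beta0, m@betaV, m@betaQ, m@betaVQ)
  g <- efficiencyGrid(seed = 24)
  fit <- fitBinomialGLM(g)
  expect_true(all(abs(fit@coefficients - truth) <= 3 * fit@se))
})
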