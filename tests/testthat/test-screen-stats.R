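test_that("the binomial GLM maximizes the likelihood it claims to", {
  # brute-force optimiser oracle on a small instance
  grid <- data.frame(v_rms = c(10, 20, 30, 10, 20, 30),
                     q_nl_s = c(20, 20, 20, 60, 60, 60),
                     successes = c(1, 3, 7, 2, 6, 9), n = 10)
  fit <- fitBinomialGLM(grid)
  ll <- function(beta) {
    p <- plogis(beta[1] + beta[2] * grid$v_rms + beta[3] * grid$q_nl_s +
                  beta[4] * grid$v_rms * grid$q_nl_s)
    sum(dbinom(grid$successes, grid$n, p, log = TRUE))
  }
  opt <- optim(c(0, 0, 0, 0), function(b) -ll(b), method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-15,
                              parscale = c(1, 0.1, 0.1, 0.005)))
  expect_equal(ll(fit@coefficients), -opt$value, tolerance = 1e-6)
  # deviance and AIC follow the full per-cell binomial convention
  ref <- glm(cbind(successes, n - successes) ~ v_rms * q_nl_s,
             family = binomial(), data = grid)
  expect_equal(fit@deviance, ref$deviance)
  expect_equal(fit@aic, AIC(ref))
  expect_false(fit@separation)
})

test_that("null grids give slope intervals covering zero and bad designs fail loudly", {
  g <- efficiencyGrid(seed = 25)
  g$successes <- 5L  # response carries no predictor information
  fit <- fitBinomialGLM(g)
  ci_lo <- fit@coefficients - 1.96 * fit@se
  ci_hi <- fit@coefficients + 1.96 * fit@se
  for (k in 2:4) expect_true(ci_lo[k] <= 0 && ci_hi[k] >= 0)
  # collinear design
  bad <- data.frame(v_rms = 30, q_nl_s = c(10, 20, 30, 40, 50),
                    successes = c(1, 2, 3, 4, 5), n = 10)
  expect_error(fitBinomialGLM(bad), "collinear|degenerate")
  expect_error(fitBinomialGLM(data.frame(v_rms = 1, q_nl_s = 1,
                                         successes = 11, n = 10)),
               "successes|at least")
  # complete separation is flagged, not returned silently
  sep <- expand.grid(v_rms = c(10, 20, 30, 40), q_nl_s = c(20, 40, 60, 80))
  sep$successes <- ifelse(sep$v_rms > 20, 10L, 0L)
  sep$n <- 10
  expect_true(fitBinomialGLM(sep)@separation)
})

test_that("inflection points solve the half-probability contour", {
  # 1-D logistic by hand: -beta0/beta1
  m1 <- new("EfficiencyModel", coefficients = c(-2, 0.5, 0, 0),
            se = rep(0.1, 4), pvalues = rep(0.01, 4),
            vcov = diag(4), deviance = 0, aic = 0, nobs = 5L,
            separation = FALSE)
  expect_equal(inflectionPoint(m1, c(Q = 0)), 4)
  # logistic symmetry about the inflection
  m <- dropletRoutingModel()
  q0 <- inflectionPoint(m, c(V = 30))
  for (d in c(1, 5, 10))
    expect_equal(actuatedSuccessProb(30, q0 + d, 1, m) +
                   actuatedSuccessProb(30, q0 - d, 1, m), 1,
                 tolerance = 1e-10)
  # the default surface crosses P = 0.5 at 51.5 nL/s when V = 27.4
  expect_equal(inflectionPoint(m, c(V = 27.4)), 51.5, tolerance = 1e-9)
  # zero effective slope is an error
  flat <- new("EfficiencyModel", coefficients = c(-2, 0.5, 0, 0),
              se = rep(0.1, 4), pvalues = rep(0.01, 4), vcov = diag(4),
              deviance = 0, aic = 0, nobs = 5L, separation = FALSE)
  expect_error(inflectionPoint(flat, c(V = 1)), "slope")
})

test_that("Poisson encapsulation math matches closed forms", {
  expect_equal(poissonOccupancy(concentration = 0.35e6,
                                dropletVolume = 1)$lambda, 0.35)
  occ <- poissonOccupancy(lambda = 0.35, nDroplets = 12600)
  expect_equal(occ$P_ge1, 1 - exp(-0.35), tolerance = 1e-10)
  expect_equal(occ$P0, exp(-0.35))
  expect_equal(occ$expected_occupied, 12600 * (1 - exp(-0.35)))
  expect_equal(poissonOccupancy(lambda = 0)$P0, 1)
  # truncated pmf sums to 1 for all lambda <= 2
  for (l in c(0.05, 0.35, 1, 2))
    expect_lt(abs(sum(poissonOccupancy(lambda = l)$pmf) - 1), 1e-10)
  expect_error(poissonOccupancy(lambda = -1), ">= 0")
})

test_that("enzymatic activity evaluates the assay formula exactly", {
  # hand evaluation: 1.9 * 0.2 * 1 * 900 / (500 * 30 * 0.025)
  expect_equal(enzymaticActivity(1000, 100, 500, VF = 0.2, DF = 1, t = 30,
                                 Vsample = 0.025), 0.912, tolerance = 1e-12)
  expect_equal(enzymaticActivity(100, 100, 500, VF = 0.2, DF = 1, t = 30,
                                 Vsample = 0.025), 0)
  # linear in the dilution factor
  a1 <- enzymaticActivity(800, 100, 450, VF = 0.2, DF = 1, t = 30,
                          Vsample = 0.025)
  a2 <- enzymaticActivity(800, 100, 450, VF = 0.2, DF = 2, t = 30,
                          Vsample = 0.025)
  expect_equal(a2, 2 * a1)
  # invariant under a common RFU rescaling
  a3 <- enzymaticActivity(8000, 1000, 4500, VF = 0.2, DF = 1, t = 30,
                          Vsample = 0.025)
  expect_equal(a3, a1)
  expect_warning(
    neg <- enzymaticActivity(50, 100, 500, VF = 0.2, DF = 1, t = 30,
                             Vsample = 0.025), "clamped")
  expect_equal(neg, 0)
  expect_error(enzymaticActivity(1000, 100, 0, VF = 0.2, DF = 1, t = 30,
                                 Vsample = 0.025), "FLUstd")
})

test_that("fold change and hyphal-exit rate are the printed ratios", {
  expect_equal(foldChange(1, 1), 1)
  expect_equal(foldChange(3.88, 0.20), 19.4)
  expect_equal(foldChange(3.88, 0.20) * foldChange(0.20, 3.88), 1)
  expect_error(foldChange(1, 0), "> 0")
  expect_equal(hyphalExitRate(0, 50), 0)
  expect_equal(hyphalExitRate(5, 50), 10)
  expect_equal(hyphalExitRate(50, 50), 100)
  expect_error(hyphalExitRate(51, 50), "exited")
})

test_that("population comparison agrees with the reference Levene test", {
  set.seed(26)
  a <- rlnorm(40); b <- rlnorm(35, sdlog = 1.6)
  cmp <- comparePopulations(a, b)
  ref <- car::leveneTest(c(a, b), factor(rep(1:2, c(40, 35))),
                         center = median)
  expect_equal(cmp$levene_statistic, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(cmp$levene_p, ref$`Pr(>F)`[1], tolerance = 1e-10)
  # identical groups: statistic 0
  expect_equal(comparePopulations(a, a)$levene_statistic, 0)
  # symmetric sample: Pearson second skewness near 0
  s <- c(-3, -2, -1, 0, 1, 2, 3)
  expect_equal(comparePopulations(s, s)$skewness_parent, 0)
  expect_error(comparePopulations(1:2, 1:10), "at least 3")
})

test_that("the binomial lower bound inverts the exact tail probability", {
  expect_equal(binomialLowerBound(0, 10, 0.999), 0)
  # bound L satisfies P(X >= s | p = L) = 1 - confidence
  for (s in c(3, 7, 9, 10)) {
    L <- binomialLowerBound(s, 10, 0.99)
    expect_equal(pbinom(s - 1, 10, L, lower.tail = FALSE), 0.01,
                 tolerance = 1e-9)
    # independent inversion of the binomial CDF
    root <- uniroot(function(p) pbinom(s - 1, 10, p, lower.tail = FALSE) -
                      0.01, c(1e-9, 1 - 1e-9), tol = 1e-12)$root
    expect_equal(L, root, tolerance = 1e-8)
  }
  # all-success closed form and the printed passive-fidelity bound
  expect_equal(binomialLowerBound(625, 625, 0.999), 0.001^(1 / 625))
  expect_gt(binomialLowerBound(625, 625, 0.999), 0.989)
  # monotone in successes
  bounds <- sapply(0:10, binomialLowerBound, n = 10, confidence = 0.99)
  expect_true(all(diff(bounds) > 0))
})
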