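#' @include AllClasses.R
NULL

#' Fit the binomial efficiency GLM
#'
#' Logit-link binomial regression of per-cell sorting successes on applied
#' potential, spacer flow and their interaction, fitted by iteratively
#' reweighted least squares (deviance convergence 1e-8). The response is
#' per-cell binomial (successes out of n), and the reported AIC uses the
#' full binomial likelihood including the combinatorial term. Complete or
#' quasi-complete separation is detected (fitted probabilities numerically
#' pinned at 0/1 alongside exploding coefficients) and flagged rather than
#' returned silently.
#'
#' @param grid data.frame with columns \code{v_rms, q_nl_s, successes, n}
#'   (>= 5 cells).
#' @param volumeCovariate optional column name of a droplet-volume
#'   covariate to include.
#' @return an [EfficiencyModel].
#' @export
fitBinomialGLM <- function(grid, volumeCovariate = NULL) {
  req <- c("v_rms", "q_nl_s", "successes", "n")
  if (!all(req %in% names(grid)))
    stop("grid needs columns: ", paste(req, collapse = ", "))
  if (nrow(grid) < 5) stop("need at least 5 grid cells")
  if (any(grid$successes < 0 | grid$successes > grid$n))
    stop("successes must lie in [0, n]")
  form <- cbind(successes, n - successes) ~ v_rms * q_nl_s
  if (!is.null(volumeCovariate))
    form <- stats::as.formula(paste(
      "cbind(successes, n - successes) ~ v_rms * q_nl_s +", volumeCovariate))
  fit <- withCallingHandlers(
    glm(form, family = binomial(), data = grid,
        control = list(epsilon = 1e-8, maxit = 100)),
    warning = function(w) invokeRestart("muffleWarning"))
  if (any(!is.finite(coef(fit))) || fit$rank < length(coef(fit)))
    stop("degenerate design: collinear predictors")
  sm <- suppressWarnings(summary(fit))
  est <- coef(fit)
  se <- sm$coefficients[, "Std. Error"]
  pv <- sm$coefficients[, "Pr(>|z|)"]
  mu <- fit$fitted.values
  sep <- any(abs(est) > 50) ||
    (any(mu > 1 - 1e-10 | mu < 1e-10) && any(se > 100))
  new("EfficiencyModel", coefficients = est, se = se, pvalues = pv,
      vcov = unname(vcov(fit)), deviance = unname(fit$deviance),
      aic = unname(AIC(fit)), nobs = nrow(grid), separation = sep)
}

#' Inflection point of a fitted efficiency surface
#'
#' Solves \code{b0 + bV V + bQ Q + bVQ V Q = 0} (success probability 0.5)
#' for the free predictor, holding the other fixed.
#'
#' @param model an [EfficiencyModel] or [RoutingModel].
#' @param fixed named scalar: \code{c(V = ...)} to solve for Q, or
#'   \code{c(Q = ...)} to solve for V.
#' @return the free predictor's value at probability 0.5.
#' @examples
#' inflectionPoint(dropletRoutingModel(), c(V = 27.4))  # 51.5 nL/s
#' @export
inflectionPoint <- function(model, fixed) {
  if (is(model, "RoutingModel")) {
    b <- c(model@beta0, model@betaV, model@betaQ, model@betaVQ)
  } else {
    b <- model@coefficients
    if (length(b) < 4) stop("model must have intercept, V, Q and V:Q terms")
  }
  what <- names(fixed)[1]
  x <- unname(fixed[1])
  if (what == "V") {
    slope <- b[3] + b[4] * x
    off <- b[1] + b[2] * x
  } else if (what == "Q") {
    slope <- b[2] + b[4] * x
    off <- b[1] + b[3] * x
  } else stop("fixed must be named V or Q")
  if (abs(slope) < 1e-12)
    stop("effective slope of the free predictor is zero at the fixed value")
  -off / slope
}

#' Poisson encapsulation summary
#'
#' Single-cell encapsulation statistics: lambda = concentration x droplet
#' volume, and the occupancy pmf P(k) = exp(-lambda) lambda^k / k!.
#'
#' @param concentration spores/mL (ignored when \code{lambda} is given).
#' @param dropletVolume droplet volume, nL.
#' @param lambda Poisson mean; computed from concentration and volume when
#'   missing.
#' @param nDroplets optional droplet count for expected-count summaries.
#' @param kMax truncation for the returned pmf.
#' @return list with \code{lambda}, \code{pmf} (k = 0..kMax), \code{P0},
#'   \code{P1}, \code{P_ge1}, \code{P_ge2}, and (when \code{nDroplets}
#'   is given) \code{expected_occupied} and \code{expected_single}.
#' @examples
#' poissonOccupancy(concentration = 0.35e6, dropletVolume = 1)$lambda  # 0.35
#' @export
poissonOccupancy <- function(concentration = NULL, dropletVolume = 1,
                             lambda = NULL, nDroplets = NULL, kMax = 50) {
  if (is.null(lambda)) {
    if (is.null(concentration)) stop("give either lambda or concentration")
    if (concentration < 0 || dropletVolume < 0)
      stop("concentration and volume must be >= 0")
    lambda <- concentration * dropletVolume * 1e-6  # 1 nL = 1e-6 mL
  }
  if (lambda < 0) stop("lambda must be >= 0")
  k <- 0:kMax
  pmf <- dpois(k, lambda)
  out <- list(lambda = lambda, pmf = setNames(pmf, k), P0 = unname(pmf[1]),
              P1 = unname(pmf[2]), P_ge1 = unname(1 - pmf[1]),
              P_ge2 = unname(1 - pmf[1] - pmf[2]))
  if (!is.null(nDroplets)) {
    out$expected_occupied <- nDroplets * out$P_ge1
    out$expected_single <- nDroplets * out$P1
  }
  out
}

#' Enzymatic activity from an endpoint fluorogenic assay
#'
#' Converts blank-corrected 4-MU fluorescence to enzyme units:
#' \deqn{A = 1.9 \cdot V_F \cdot DF \cdot (FLU - FLU_{blank}) /
#'   (FLU_{std} \cdot t \cdot V_{sample})}
#' where 1.9 nmol/mL is the amount of 4-MU standard, V_F the final
#' reaction volume (mL), DF the dilution factor, FLU_std the standard's
#' blank-corrected fluorescence, t the incubation time (min) and V_sample
#' the sample volume (mL). One unit releases 1 umol of 4-MU per minute.
#' A negative blank-corrected fluorescence clamps to zero activity with a
#' warning (an assay cannot show negative release).
#'
#' @param FLU well fluorescence, RFU.
#' @param FLUblank substrate-blank fluorescence, RFU.
#' @param FLUstd standard fluorescence minus its blank, RFU (> 0).
#' @param VF final reaction volume, mL.
#' @param DF dilution factor (>= 1).
#' @param t incubation time, min.
#' @param Vsample sample volume, mL.
#' @param standardAmount amount of standard, nmol/mL.
#' @return activity in U/mL (vectorised).
#' @examples
#' enzymaticActivity(1000, 100, 500, VF = 0.2, DF = 1, t = 30,
#'                   Vsample = 0.025)  # 0.912 U/mL
#' @export
enzymaticActivity <- function(FLU, FLUblank, FLUstd, VF, DF = 1, t = 30,
                              Vsample, standardAmount = 1.9) {
  if (any(FLUstd <= 0)) stop("FLUstd must be > 0")
  if (any(t <= 0)) stop("t must be > 0")
  if (any(VF <= 0) || any(Vsample <= 0)) stop("volumes must be > 0")
  if (any(DF < 1)) stop("DF must be >= 1")
  d <- FLU - FLUblank
  if (any(d < 0)) {
    warning("negative blank-corrected fluorescence clamped to zero activity")
    d <- pmax(d, 0)
  }
  standardAmount * VF * DF * d / (FLUstd * t * Vsample)
}

#' Fold change relative to a reference activity
#'
#' @param sample sample activity.
#' @param reference reference (e.g. wild-type) activity, > 0.
#' @return sample / reference.
#' @export
foldChange <- function(sample, reference) {
  if (any(reference <= 0)) stop("reference activity must be > 0")
  sample / reference
}

#' Hyphal-exit rate
#'
#' Percentage of droplets with hyphae exiting, out of all droplets
#' including empty ones.
#'
#' @param exited droplets with an exited hyphal tip.
#' @param total total droplet count (> 0), including empty droplets.
#' @return percentage.
#' @export
hyphalExitRate <- function(exited, total) {
  if (any(total <= 0)) stop("total must be > 0")
  if (any(exited < 0) || any(exited > total))
    stop("exited must lie in [0, total]")
  100 * exited / total
}

# Brown-Forsythe statistic: one-way F on absolute deviations from the
# group medians -- the median-centred Levene variant, robust for skewed
# fluorescence distributions.
.brown_forsythe <- function(groups) {
  z <- lapply(groups, function(x) abs(x - median(x)))
  ni <- lengths(z)
  N <- sum(ni); k <- length(z)
  zi <- vapply(z, mean, 0)
  zbar <- sum(ni * zi) / N
  ssb <- sum(ni * (zi - zbar)^2)
  ssw <- sum(vapply(seq_len(k), function(i) sum((z[[i]] - zi[i])^2), 0))
  if (ssw == 0) {
    stat <- if (ssb == 0) 0 else Inf
  } else {
    stat <- (N - k) / (k - 1) * ssb / ssw
  }
  p <- if (is.finite(stat)) pf(stat, k - 1, N - k, lower.tail = FALSE) else 0
  list(statistic = stat, p.value = p, df = c(k - 1, N - k))
}

#' Compare parent and mutant fluorescence populations
#'
#' The two screening diagnostics: a median-centred Levene (Brown-Forsythe)
#' test for a difference in variance between parent and mutant peak
#' intensities, and Pearson's second skewness coefficient
#' \code{3 (mean - median) / sd} per group (mutant libraries skew right of
#' the parent strain).
#'
#' @param parent parent-strain peak intensities (>= 3 values).
#' @param mutant mutant-library peak intensities (>= 3 values).
#' @return list with \code{levene_statistic}, \code{levene_p},
#'   \code{skewness_parent}, \code{skewness_mutant}.
#' @export
comparePopulations <- function(parent, mutant) {
  if (length(parent) < 3 || length(mutant) < 3)
    stop("each group needs at least 3 values")
  lev <- .brown_forsythe(list(parent, mutant))
  skew <- function(x) {
    s <- sd(x)
    if (s == 0) 0 else 3 * (mean(x) - median(x)) / s
  }
  list(levene_statistic = lev$statistic, levene_p = lev$p.value,
       skewness_parent = skew(parent), skewness_mutant = skew(mutant))
}

#' One-sided exact lower confidence bound for a binomial proportion
#'
#' Clopper-Pearson-style bound: the smallest p whose upper tail still
#' contains the observed success count at the stated confidence. With all
#' trials successful the bound is \code{(1 - confidence)^(1/n)}.
#'
#' @param successes observed successes.
#' @param n trials.
#' @param confidence confidence level in (0, 1).
#' @return lower bound on the success probability.
#' @examples
#' binomialLowerBound(625, 625, 0.999)  # ~0.989
#' @export
binomialLowerBound <- function(successes, n, confidence = 0.999) {
  if (successes < 0 || successes > n) stop("successes must lie in [0, n]")
  if (confidence <= 0 || confidence >= 1) stop("confidence must be in (0, 1)")
  if (successes == 0) return(0)
  qbeta(1 - confidence, successes, n - successes + 1)
}
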