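#' @include AllClasses.R
NULL

#' Calibrate the default routing model from its anchors
#'
#' The default logistic surface is pinned by two printed anchors -- success
#' probability 0.5 at (27.4 V_RMS, 51.5 nL/s, 1 nL) and ~0.99 in the
#' efficient screening regime (40 V_RMS, 60 nL/s) -- which leave two
#' degrees of freedom for the four (V, Q) coefficients. These are resolved
#' by fixing the voltage main effect and the voltage at which the flow
#' slope changes sign (\code{vStar}): below \code{vStar} more flow hurts
#' (the E1 topology: pulsed droplets dragged into the main channel), above
#' it more flow helps (the E2 topology: too little drag to commit to the
#' disfavored channel). Success is monotone increasing in V at every flow
#' in the characterized range.
#'
#' @param betaV voltage main effect, per V_RMS.
#' @param vStar flow-slope sign-change voltage, V_RMS.
#' @param anchor50 c(V, Q) of the P = 0.5 inflection anchor.
#' @param anchorHigh c(V, Q, P) of the efficient-regime anchor.
#' @param betaVol volume coefficient, per nL (centred at 1 nL; negative:
#'   smaller droplets sort more reliably).
#' @param passiveFidelity80,passiveFidelity60 passive main-channel
#'   probabilities at 80 and 60 nL/s.
#' @param vLow,qLow failure-regime classification thresholds.
#' @return a [RoutingModel].
#' @export
calibrateRoutingModel <- function(betaV = 0.15, vStar = 20,
                                  anchor50 = c(27.4, 51.5),
                                  anchorHigh = c(40, 60, 0.99),
                                  betaVol = -3,
                                  passiveFidelity80 = 0.995,
                                  passiveFidelity60 = 0.992,
                                  vLow = 27.4, qLow = 51.5) {
  V1 <- anchor50[1]; Q1 <- anchor50[2]
  V2 <- anchorHigh[1]; Q2 <- anchorHigh[2]
  L <- qlogis(anchorHigh[3])
  denom <- -vStar * (Q2 - Q1) + (V2 * Q2 - V1 * Q1)
  betaVQ <- (L - betaV * (V2 - V1)) / denom
  betaQ <- -vStar * betaVQ
  beta0 <- -(betaV * V1 + betaQ * Q1 + betaVQ * V1 * Q1)
  new("RoutingModel", beta0 = beta0, betaV = betaV, betaQ = betaQ,
      betaVQ = betaVQ, betaVol = betaVol,
      passiveFidelity80 = passiveFidelity80,
      passiveFidelity60 = passiveFidelity60, vLow = vLow, qLow = qLow)
}

#' Default routing model
#'
#' Loads the versioned default coefficients shipped with the package
#' (\code{inst/extdata/routing_model_default.yaml}); these equal the output
#' of [calibrateRoutingModel()] with default arguments.
#'
#' @return a [RoutingModel].
#' @examples
#' m <- dropletRoutingModel()
#' actuatedSuccessProb(27.4, 51.5, 1, m)  # 0.5
#' @export
dropletRoutingModel <- function() {
  path <- system.file("extdata", "routing_model_default.yaml",
                      package = "dropScreen", mustWork = TRUE)
  y <- yaml::read_yaml(path)
  new("RoutingModel", beta0 = y$beta0, betaV = y$betaV, betaQ = y$betaQ,
      betaVQ = y$betaVQ, betaVol = y$betaVol,
      passiveFidelity80 = y$passive_fidelity_80,
      passiveFidelity60 = y$passive_fidelity_60,
      vLow = y$v_low, qLow = y$q_low)
}

#' Actuated sorting success probability
#'
#' Deterministic logistic surface:
#' \code{plogis(b0 + bV V + bQ Q + bVQ V Q + bVol (volume - 1))}.
#'
#' @param V applied potential, V_RMS.
#' @param Q spacer oil flow, nL/s.
#' @param volume droplet volume, nL.
#' @param model a [RoutingModel].
#' @return success probability (vectorised).
#' @export
actuatedSuccessProb <- function(V, Q, volume = 1,
                                model = dropletRoutingModel()) {
  if (any(V < 0) || any(Q < 0) || any(volume < 0))
    stop("V, Q and volume must be >= 0")
  plogis(model@beta0 + model@betaV * V + model@betaQ * Q +
           model@betaVQ * V * Q + model@betaVol * (volume - 1))
}

#' Passive routing fidelity
#'
#' Probability that an unpulsed droplet takes the wide main channel, as a
#' function of the spacer oil flow: the calibrated values at 60 and 80 nL/s
#' with linear interpolation between them, a plateau down to 10 nL/s, and
#' a linear collapse below 10 nL/s where large plugs raise the main-channel
#' resistance and droplets start drifting into the disfavored channel.
#'
#' @param Q spacer oil flow, nL/s (vectorised).
#' @param model a [RoutingModel].
#' @return main-channel probability.
#' @export
passiveFidelity <- function(Q, model = dropletRoutingModel()) {
  p60 <- model@passiveFidelity60
  p80 <- model@passiveFidelity80
  ifelse(Q >= 80, p80,
    ifelse(Q >= 60, p60 + (p80 - p60) * (Q - 60) / 20,
      ifelse(Q >= 10, p60, 0.5 + (p60 - 0.5) * Q / 10)))
}

#' Route droplets through the Y-junction
#'
#' Stochastic outcome model. Unpulsed droplets enter the main channel with
#' the passive fidelity at the given flow, otherwise drift into the
#' disfavored channel (a passive false positive). Pulsed droplets enter
#' the disfavored channel with [actuatedSuccessProb()]; on failure the mode
#' is classified from the operating regime: E1 (escapes into the main
#' channel) at low potential, E2 (abandons/stalls) at low flow, and E3
#' (merges with the next arrival) substituted when the inter-droplet gap is
#' shorter than the pulse and the potential is above the E1 regime. One
#' uniform draw per droplet, indexed by position, so matched runs sharing a
#' seed reuse identical draws for unpulsed droplets.
#'
#' @param train a [DropletTrain] (or integer count \code{n}).
#' @param pulsed logical vector (recycled): was the PE fired for this
#'   droplet?
#' @param V applied potential, V_RMS.
#' @param Q spacer oil flow, nL/s.
#' @param model a [RoutingModel].
#' @param pulseDuration PE pulse duration, s (E3 gap rule).
#' @param nextGap time to the next arrival, s; computed from the train when
#'   available.
#' @param seed integer seed.
#' @return the train with \code{routed_channel} and \code{failure_mode}
#'   filled (or a data.frame of the two columns when \code{train} is a
#'   count).
#' @export
routeDroplets <- function(train, pulsed, V, Q,
                          model = dropletRoutingModel(),
                          pulseDuration = 0.3, nextGap = NULL, seed = 1L) {
  is_train <- is(train, "DropletTrain")
  n <- if (is_train) nrow(train) else as.integer(train)
  volume <- if (is_train) train$volume else rep(1, n)
  if (is.null(nextGap)) {
    nextGap <- if (is_train && n > 1)
      c(diff(train$arrival_time), Inf) else rep(Inf, n)
  }
  pulsed <- rep_len(pulsed, n)
  set.seed(seed)
  u <- runif(n)
  p_act <- actuatedSuccessProb(V, Q, volume, model)
  p_pass <- passiveFidelity(Q, model)
  channel <- character(n)
  mode <- rep("none", n)
  unp <- !pulsed
  channel[unp] <- ifelse(u[unp] < p_pass, "main", "disfavored")
  act <- which(pulsed)
  ok <- u[act] < p_act[act]
  channel[act[ok]] <- "disfavored"
  fail <- act[!ok]
  if (length(fail)) {
    m <- ifelse(Q < model@qLow, "E2",
                ifelse(V < model@vLow, "E1", "E1"))
    m <- rep_len(m, length(fail))
    e3 <- nextGap[fail] < pulseDuration & V >= model@vLow
    m[e3] <- "E3"
    mode[fail] <- m
    channel[fail] <- ifelse(m == "E3", "merged", "main")
  }
  if (!is_train)
    return(data.frame(routed_channel = channel, failure_mode = mode))
  .set_cols(train, routed_channel = channel, failure_mode = mode)
}

#' Run the sorter-characterization grid experiment
#'
#' The two-factor efficiency design: 7 potential levels crossed with 20
#' spacer-flow levels, N actuated sorting attempts per cell, successes
#' drawn Binomial(N, [actuatedSuccessProb()]). Feeding the result to
#' [fitBinomialGLM()] closes the parameter-recovery loop.
#'
#' @param vLevels potentials, V_RMS (default 7 levels spanning 4.6-51.8).
#' @param qLevels flows, nL/s (default 20 levels spanning 5-100).
#' @param N attempts per cell.
#' @param model a [RoutingModel].
#' @param volume droplet volume, nL.
#' @param seed integer seed.
#' @return data.frame with columns \code{v_rms, q_nl_s, successes, n}.
#' @export
efficiencyGrid <- function(vLevels = seq(4.6, 51.8, length.out = 7),
                           qLevels = seq(5, 100, length.out = 20),
                           N = 10, model = dropletRoutingModel(),
                           volume = 1, seed = 1L) {
  if (N < 1) stop("N must be >= 1")
  grid <- expand.grid(v_rms = vLevels, q_nl_s = qLevels,
                      KEEP.OUT.ATTRS = FALSE)
  p <- actuatedSuccessProb(grid$v_rms, grid$q_nl_s, volume, model)
  set.seed(seed)
  grid$successes <- rbinom(nrow(grid), N, p)
  grid$n <- N
  grid
}
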