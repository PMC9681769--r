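#' @include AllGenerics.R
NULL

#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importClassesFrom S4Vectors DFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats rnorm runif rpois rlnorm rexp rbinom quantile median sd
#'   plogis qlogis glm binomial coef vcov pchisq pf pbeta qbeta dpois ppoints
#'   AIC logLik setNames
#' @importFrom utils read.csv write.csv head
#' @useDynLib dropScreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.media_levels <- c("MM", "G1", "CC1_G1", "CC1_G01", "CCMM")
.substrate_levels <- c("FL_GlcNAc", "FL_GalNAc", "FD_Glc")
.channel_levels <- c("main", "disfavored", "merged", "burst", "unrouted")
.failure_levels <- c("none", "E1", "E2", "E3")

# ---------------------------------------------------------------------------
# Simulator configuration
# ---------------------------------------------------------------------------

#' Simulator configuration
#'
#' Bundles every knob of the synthetic droplet-train generator. Defaults are
#' the screening-session conditions: 7 droplets per second, Poisson spore
#' occupancy with mean 0.35 (0.35e6 spores/mL in ~1 nL droplets), ~1 nL
#' droplets with 5% volume CV before incubation, colloidal-chitin minimal
#' medium, and a fluorescein-linked GlcNAc substrate at a 100 uM in-droplet
#' ceiling.
#'
#' @slot dropletRate droplet arrival rate, events/s.
#' @slot sessionLength simulated session length, s.
#' @slot occupancyLambda Poisson mean spores per droplet.
#' @slot sporeConcentration spores/mL; when finite it overrides
#'   \code{occupancyLambda} as concentration x mean volume.
#' @slot dropletVolumeMean mean droplet volume, nL.
#' @slot volumeCV coefficient of variation of droplet volume
#'   (polydispersity; grows with incubation).
#' @slot incubationTime incubation time, h.
#' @slot media one of MM, G1, CC1_G1, CC1_G01, CCMM.
#' @slot substrate one of FL_GlcNAc, FL_GalNAc, FD_Glc.
#' @slot mutantFraction fraction of occupied droplets carrying a mutant
#'   clone with a heavy-tailed activity multiplier.
#' @slot seed integer seed controlling every draw.
#' @slot arrivalMode "dead_time" (default: shifted-exponential renewal gaps,
#'   physically non-overlapping plugs), "poisson" (homogeneous) or "regular".
#' @slot minGap dead time between arrivals in dead_time mode, s.
#' @slot transitTime droplet transit duration through the detection spot, s.
#' @slot backgroundUM substrate background fluorescein-equivalent, uM.
#' @slot substrateCeilingUM in-droplet substrate concentration, uM; the
#'   saturation ceiling of fluorescein accumulation.
#' @slot activityMedian median wild-type fluorescein production rate among
#'   occupied droplets, uM/h.
#' @slot activitySdlog lognormal sdlog of clone-to-clone activity.
#' @slot mutantEffectSdlog lognormal sdlog of the mutant activity multiplier
#'   (median 1, right-skewed).
#' @export
setClass("SimConfig", representation(
  dropletRate = "numeric", sessionLength = "numeric",
  occupancyLambda = "numeric", sporeConcentration = "numeric",
  dropletVolumeMean = "numeric", volumeCV = "numeric",
  incubationTime = "numeric", media = "character", substrate = "character",
  mutantFraction = "numeric", seed = "integer", arrivalMode = "character",
  minGap = "numeric", transitTime = "numeric", backgroundUM = "numeric",
  substrateCeilingUM = "numeric", activityMedian = "numeric",
  activitySdlog = "numeric", mutantEffectSdlog = "numeric"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@dropletRate <= 0) msg <- c(msg, "dropletRate must be > 0")
  if (object@sessionLength <= 0) msg <- c(msg, "sessionLength must be > 0")
  if (object@occupancyLambda < 0) msg <- c(msg, "occupancyLambda must be >= 0")
  if (object@dropletVolumeMean <= 0) msg <- c(msg, "dropletVolumeMean must be > 0")
  if (object@volumeCV < 0) msg <- c(msg, "volumeCV must be >= 0")
  if (object@incubationTime < 0) msg <- c(msg, "incubationTime must be >= 0")
  if (object@mutantFraction < 0 || object@mutantFraction > 1)
    msg <- c(msg, "mutantFraction must be in [0, 1]")
  if (!object@media %in% .media_levels)
    msg <- c(msg, paste("media must be one of:", paste(.media_levels, collapse = ", ")))
  if (!object@substrate %in% .substrate_levels)
    msg <- c(msg, paste("substrate must be one of:", paste(.substrate_levels, collapse = ", ")))
  if (!object@arrivalMode %in% c("dead_time", "poisson", "regular"))
    msg <- c(msg, "arrivalMode must be dead_time, poisson or regular")
  if (object@transitTime <= 0) msg <- c(msg, "transitTime must be > 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn SimConfig constructor.
#' @param dropletRate,sessionLength,occupancyLambda,sporeConcentration,dropletVolumeMean,volumeCV,incubationTime,media,substrate,mutantFraction,seed,arrivalMode,minGap,transitTime,backgroundUM,substrateCeilingUM,activityMedian,activitySdlog,mutantEffectSdlog see slots.
#' @return a \code{SimConfig} object.
#' @examples
#' cfg <- simConfig(sessionLength = 60, seed = 1)
#' cfg
#' @export
simConfig <- function(dropletRate = 7, sessionLength = 1800,
                      occupancyLambda = 0.35, sporeConcentration = NA_real_,
                      dropletVolumeMean = 1.0, volumeCV = 0.05,
                      incubationTime = 48, media = "CCMM",
                      substrate = "FL_GlcNAc", mutantFraction = 0.1,
                      seed = 1L, arrivalMode = "dead_time", minGap = 0.1,
                      transitTime = 0.04, backgroundUM = 5,
                      substrateCeilingUM = 100, activityMedian = 1,
                      activitySdlog = 0.5, mutantEffectSdlog = 0.8) {
  if (is.finite(sporeConcentration)) {
    if (sporeConcentration < 0) stop("sporeConcentration must be >= 0")
    # spores/mL x nL: 1 nL = 1e-6 mL
    occupancyLambda <- sporeConcentration * dropletVolumeMean * 1e-6
  }
  new("SimConfig", dropletRate = dropletRate, sessionLength = sessionLength,
      occupancyLambda = occupancyLambda, sporeConcentration = sporeConcentration,
      dropletVolumeMean = dropletVolumeMean, volumeCV = volumeCV,
      incubationTime = incubationTime, media = media, substrate = substrate,
      mutantFraction = mutantFraction, seed = as.integer(seed),
      arrivalMode = arrivalMode, minGap = minGap, transitTime = transitTime,
      backgroundUM = backgroundUM, substrateCeilingUM = substrateCeilingUM,
      activityMedian = activityMedian, activitySdlog = activitySdlog,
      mutantEffectSdlog = mutantEffectSdlog)
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@dropletRate, "droplets/s for",
      object@sessionLength, "s\n")
  cat("  occupancy lambda:", object@occupancyLambda,
      "| volume:", object@dropletVolumeMean, "nL (CV",
      object@volumeCV, ")\n")
  cat("  media:", object@media, "| substrate:", object@substrate,
      "| incubation:", object@incubationTime, "h\n")
  cat("  arrivals:", object@arrivalMode, "| seed:", object@seed, "\n")
})

# ---------------------------------------------------------------------------
# Detector model
# ---------------------------------------------------------------------------

#' Spectrometer model for stream synthesis
#'
#' Describes the simulated CCD spectrometer: a fixed wavelength grid
#' (default 450-650 nm at 0.5 nm, covering the 500-600 nm recording window
#' plus the 470 nm excitation bleed-through), a frame period, a dark
#' spectrum, Gaussian read noise, and the fluorescein emission band shape.
#'
#' @slot wavelengthGrid strictly increasing wavelengths, nm.
#' @slot framePeriod spectrometer integration period, s.
#' @slot darkSpectrum dark/background intensity per wavelength, RFU
#'   (includes the excitation bleed-through band).
#' @slot noiseSD Gaussian read-noise standard deviation, RFU.
#' @slot emissionCenter fluorescein emission centre, nm.
#' @slot emissionWidthSD Gaussian emission band sd, nm.
#' @slot gainRFUperUM detector gain: peak RFU per uM fluorescein.
#' @export
setClass("DetectorModel", representation(
  wavelengthGrid = "numeric", framePeriod = "numeric",
  darkSpectrum = "numeric", noiseSD = "numeric", emissionCenter = "numeric",
  emissionWidthSD = "numeric", gainRFUperUM = "numeric"))

setValidity("DetectorModel", function(object) {
  msg <- character()
  if (any(diff(object@wavelengthGrid) <= 0))
    msg <- c(msg, "wavelengthGrid must be strictly increasing")
  if (object@framePeriod <= 0) msg <- c(msg, "framePeriod must be > 0")
  if (object@noiseSD < 0) msg <- c(msg, "noiseSD must be >= 0")
  if (length(object@darkSpectrum) != length(object@wavelengthGrid))
    msg <- c(msg, "darkSpectrum must match the wavelength grid")
  if (length(msg)) msg else TRUE
})

#' @describeIn DetectorModel constructor. The default dark spectrum is a
#'   flat 60 RFU offset plus a 470 nm excitation bleed-through band.
#' @param wavelengthGrid,framePeriod,noiseSD,emissionCenter,emissionWidthSD,gainRFUperUM see slots.
#' @param darkLevel flat dark offset, RFU.
#' @param bleedthroughCenter excitation bleed-through centre, nm.
#' @param bleedthroughAmplitude bleed-through band amplitude, RFU.
#' @param bleedthroughSD bleed-through band sd, nm.
#' @return a \code{DetectorModel}.
#' @export
detectorModel <- function(wavelengthGrid = seq(450, 650, by = 0.5),
                          framePeriod = 0.010, darkLevel = 60, noiseSD = 3,
                          emissionCenter = 515, emissionWidthSD = 15,
                          gainRFUperUM = 20, bleedthroughCenter = 470,
                          bleedthroughAmplitude = 50, bleedthroughSD = 5) {
  dark <- darkLevel + bleedthroughAmplitude *
    exp(-0.5 * ((wavelengthGrid - bleedthroughCenter) / bleedthroughSD)^2)
  new("DetectorModel", wavelengthGrid = wavelengthGrid,
      framePeriod = framePeriod, darkSpectrum = dark, noiseSD = noiseSD,
      emissionCenter = emissionCenter, emissionWidthSD = emissionWidthSD,
      gainRFUperUM = gainRFUperUM)
}

setMethod("show", "DetectorModel", function(object) {
  g <- object@wavelengthGrid
  cat("DetectorModel:", length(g), "channels,", min(g), "-", max(g),
      "nm | frame", object@framePeriod * 1000, "ms | noise sd",
      object@noiseSD, "RFU\n")
})

# ---------------------------------------------------------------------------
# Droplet train
# ---------------------------------------------------------------------------

#' Ground-truth droplet train
#'
#' A \code{DFrame} subclass holding one row per simulated droplet: arrival
#' time (s), volume (nL), spore occupancy, fluorescein production rate
#' (uM/h), fluorescein concentration at reinjection (uM), true class,
#' hyphal-exit time (h, NA when the droplet never exits), routed channel
#' and failure mode. The generating \code{SimConfig} rides along in
#' \code{metadata()}.
#'
#' @export
setClass("DropletTrain", contains = "DFrame")

setValidity("DropletTrain", function(object) {
  req <- c("id", "arrival_time", "volume", "n_spores", "activity_rate",
           "fluorescein_conc", "true_positive", "hyphal_exit_time",
           "routed_channel", "failure_mode")
  msg <- character()
  miss <- setdiff(req, colnames(object))
  if (length(miss))
    msg <- c(msg, paste("missing columns:", paste(miss, collapse = ", ")))
  else {
    if (any(object$n_spores < 0)) msg <- c(msg, "n_spores must be >= 0")
    if (any(object$fluorescein_conc < 0))
      msg <- c(msg, "fluorescein_conc must be >= 0")
    if (any(!object$routed_channel %in% .channel_levels))
      msg <- c(msg, "invalid routed_channel")
    if (any(!object$failure_mode %in% .failure_levels))
      msg <- c(msg, "invalid failure_mode")
    if (is.unsorted(object$arrival_time))
      msg <- c(msg, "arrival_time must be non-decreasing")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "DropletTrain", function(object) {
  n <- nrow(object)
  occ <- sum(object$n_spores > 0)
  cat("DropletTrain with", n, "droplets |", occ, "occupied (",
      if (n) round(100 * occ / n, 1) else 0, "%)\n")
  callNextMethod()
})

# ---------------------------------------------------------------------------
# Spectral frames
# ---------------------------------------------------------------------------

#' Spectrometer frame stream
#'
#' A \code{SummarizedExperiment} subclass: one assay \code{"intensity"}
#' (wavelengths x frames, RFU), \code{rowData()$wavelength} in nm and
#' \code{colData()$time} in seconds.
#'
#' @export
setClass("SpectralFrames", contains = "SummarizedExperiment")

setValidity("SpectralFrames", function(object) {
  msg <- character()
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  wl <- rowData(object)$wavelength
  tm <- colData(object)$time
  if (is.null(wl) || any(diff(wl) <= 0))
    msg <- c(msg, "rowData()$wavelength must be strictly increasing")
  if (is.null(tm) || (length(tm) > 1 && any(diff(tm) <= 0)))
    msg <- c(msg, "colData()$time must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' @describeIn SpectralFrames constructor.
#' @param intensity wavelengths x frames matrix, RFU.
#' @param wavelength wavelength grid, nm.
#' @param time frame times, s.
#' @return a \code{SpectralFrames} object.
#' @export
SpectralFrames <- function(intensity, wavelength, time) {
  intensity <- as.matrix(intensity)
  dimnames(intensity) <- NULL
  se <- SummarizedExperiment(
    assays = list(intensity = intensity),
    rowData = S4Vectors::DataFrame(wavelength = wavelength),
    colData = S4Vectors::DataFrame(time = time))
  new("SpectralFrames", se)
}

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "SpectralFrames", function(x) rowData(x)$wavelength)

#' @rdname frameTimes
#' @export
setMethod("frameTimes", "SpectralFrames", function(x) colData(x)$time)

#' @rdname intensityMatrix
#' @export
setMethod("intensityMatrix", "SpectralFrames",
          function(x) assay(x, "intensity"))

setMethod("show", "SpectralFrames", function(object) {
  cat("SpectralFrames:", ncol(object), "frames x", nrow(object),
      "wavelengths (", min(wavelengths(object)), "-",
      max(wavelengths(object)), "nm )\n")
  tm <- frameTimes(object)
  if (length(tm)) cat("  time:", min(tm), "-", max(tm), "s\n")
})

# ---------------------------------------------------------------------------
# Signal-processing settings
# ---------------------------------------------------------------------------

#' Butterworth denoising settings
#'
#' Third-order lowpass at 0.1 normalised cutoff by default, applied causally
#' along the wavelength axis of each frame.
#'
#' @slot order filter order (>= 1).
#' @slot cutoff normalised cutoff frequency in (0, 1), Nyquist = 1.
#' @export
setClass("FilterSettings",
         representation(order = "integer", cutoff = "numeric"))

setValidity("FilterSettings", function(object) {
  msg <- character()
  if (object@order < 1) msg <- c(msg, "order must be >= 1")
  if (object@cutoff <= 0 || object@cutoff >= 1)
    msg <- c(msg, "cutoff must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' @describeIn FilterSettings constructor.
#' @param order,cutoff see slots.
#' @export
filterSettings <- function(order = 3, cutoff = 0.1)
  new("FilterSettings", order = as.integer(order), cutoff = cutoff)

#' Peak detection criteria
#'
#' The four retained-peak criteria: height, base width, separation from
#' neighbouring peaks, and topographic prominence.
#'
#' @slot minHeight minimum peak intensity, RFU.
#' @slot minBaseWidth minimum base width, nm.
#' @slot minDistance minimum wavelength separation between retained peaks, nm.
#' @slot minProminence minimum topographic prominence, RFU.
#' @export
setClass("PeakCriteria", representation(
  minHeight = "numeric", minBaseWidth = "numeric", minDistance = "numeric",
  minProminence = "numeric"))

setValidity("PeakCriteria", function(object) {
  v <- c(object@minHeight, object@minBaseWidth, object@minDistance,
         object@minProminence)
  if (any(v < 0)) "all criteria must be >= 0" else TRUE
})

#' @describeIn PeakCriteria constructor.
#' @param minHeight,minBaseWidth,minDistance,minProminence see slots.
#' @export
peakCriteria <- function(minHeight = 50, minBaseWidth = 2, minDistance = 5,
                         minProminence = 25)
  new("PeakCriteria", minHeight = minHeight, minBaseWidth = minBaseWidth,
      minDistance = minDistance, minProminence = minProminence)

#' Sorting gate
#'
#' Wavelength window, intensity window and noise floor applied to detected
#' event peaks. Both intervals are closed; "above the noise level" is
#' strict. The default wavelength window is 510-520 nm; a wider 500-520 nm
#' preset is available via \code{gatePreset("wide")}.
#'
#' @slot wavelengthMin,wavelengthMax window in nm.
#' @slot intensityMin,intensityMax window in RFU (\code{Inf} allowed).
#' @slot noiseLevel noise floor in RFU (strict lower bound).
#' @export
setClass("Gate", representation(
  wavelengthMin = "numeric", wavelengthMax = "numeric",
  intensityMin = "numeric", intensityMax = "numeric",
  noiseLevel = "numeric"))

setValidity("Gate", function(object) {
  msg <- character()
  if (object@wavelengthMin >= object@wavelengthMax)
    msg <- c(msg, "wavelengthMin must be < wavelengthMax")
  if (object@intensityMin >= object@intensityMax)
    msg <- c(msg, "intensityMin must be < intensityMax")
  if (object@intensityMin < object@noiseLevel)
    msg <- c(msg, "intensityMin must be >= noiseLevel")
  if (length(msg)) msg else TRUE
})

#' @describeIn Gate constructor.
#' @param wavelengthMin,wavelengthMax,intensityMin,intensityMax,noiseLevel see slots.
#' @export
gate <- function(wavelengthMin = 510, wavelengthMax = 520, intensityMin = 50,
                 intensityMax = Inf, noiseLevel = 0)
  new("Gate", wavelengthMin = wavelengthMin, wavelengthMax = wavelengthMax,
      intensityMin = intensityMin, intensityMax = intensityMax,
      noiseLevel = noiseLevel)

setMethod("show", "Gate", function(object) {
  cat("Gate: wavelength [", object@wavelengthMin, ",", object@wavelengthMax,
      "] nm | intensity [", object@intensityMin, ",", object@intensityMax,
      "] RFU | noise >", object@noiseLevel, "\n")
})

# ---------------------------------------------------------------------------
# Controller settings
# ---------------------------------------------------------------------------

#' Pulsing-electrode settings
#'
#' A 300 ms, 10 kHz sine pulse by default; amplitude in V_RMS.
#'
#' @slot duration pulse duration, s.
#' @slot frequency sine frequency, Hz.
#' @slot amplitude amplitude, V_RMS.
#' @export
setClass("PulseSettings", representation(
  duration = "numeric", frequency = "numeric", amplitude = "numeric"))

setValidity("PulseSettings", function(object) {
  msg <- character()
  if (object@duration <= 0) msg <- c(msg, "duration must be > 0")
  if (object@amplitude < 0) msg <- c(msg, "amplitude must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn PulseSettings constructor.
#' @param duration,frequency,amplitude see slots.
#' @export
pulseSettings <- function(duration = 0.3, frequency = 1e4, amplitude = 15)
  new("PulseSettings", duration = duration, frequency = frequency,
      amplitude = amplitude)

#' Travel-time model
#'
#' Droplet travel time between the detection spot and the sorting junction,
#' tau = k / Q, with k calibrated so that tau = 0.1 s at a total oil flow of
#' 30 nL/s.
#'
#' @slot travelConstant k, nL.
#' @slot oilFlow total oil flow Q, nL/s.
#' @export
setClass("TimingModel",
         representation(travelConstant = "numeric", oilFlow = "numeric"))

setValidity("TimingModel", function(object) {
  msg <- character()
  if (object@travelConstant <= 0) msg <- c(msg, "travelConstant must be > 0")
  if (object@oilFlow <= 0) msg <- c(msg, "oilFlow must be > 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn TimingModel constructor.
#' @param travelConstant,oilFlow see slots.
#' @export
timingModel <- function(travelConstant = 3.0, oilFlow = 30)
  new("TimingModel", travelConstant = travelConstant, oilFlow = oilFlow)

#' Sort-session log
#'
#' A \code{DFrame} subclass with one row per droplet event seen by the
#' controller: detection time, gated flag, whether a pulse was issued, the
#' pulse start time, and a merge-risk flag for gated events arriving during
#' an active pulse. Session counters live in \code{metadata()}.
#'
#' @export
setClass("SortLog", contains = "DFrame")

setValidity("SortLog", function(object) {
  req <- c("event_id", "detect_time", "gated", "pulse_issued", "pulse_start",
           "merge_risk")
  miss <- setdiff(req, colnames(object))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  ps <- object$pulse_start[object$pulse_issued]
  if (length(ps) > 1 && any(diff(sort(ps)) <= 0))
    return("pulse starts must be distinct")
  TRUE
})

setMethod("show", "SortLog", function(object) {
  cat("SortLog:", nrow(object), "events |", sum(object$gated), "gated |",
      sum(object$pulse_issued), "pulses |", sum(object$merge_risk),
      "merge-risk\n")
  callNextMethod()
})

# ---------------------------------------------------------------------------
# Sorter outcome model
# ---------------------------------------------------------------------------

#' Electrostatic sorter routing model
#'
#' Logistic model of actuated sorting success over applied potential V
#' (V_RMS), spacer oil flow Q (nL/s), their interaction and droplet volume,
#' plus passive routing fidelity and the regime thresholds used to classify
#' the failure modes E1 (pulsed droplet escapes into the main channel; low
#' potential, high flow), E2 (droplet abandons or stalls at the disfavored
#' channel; low flow) and E3 (merge with the next arrival; pulse still
#' active when it reaches the junction).
#'
#' @slot beta0 intercept.
#' @slot betaV coefficient per V_RMS.
#' @slot betaQ coefficient per nL/s.
#' @slot betaVQ interaction coefficient.
#' @slot betaVol coefficient per nL of volume (centred at 1 nL).
#' @slot passiveFidelity80 probability an unpulsed droplet takes the main
#'   channel at 80 nL/s.
#' @slot passiveFidelity60 same at 60 nL/s.
#' @slot vLow regime threshold for E1 classification, V_RMS.
#' @slot qLow regime threshold for E2 classification, nL/s.
#' @export
setClass("RoutingModel", representation(
  beta0 = "numeric", betaV = "numeric", betaQ = "numeric",
  betaVQ = "numeric", betaVol = "numeric", passiveFidelity80 = "numeric",
  passiveFidelity60 = "numeric", vLow = "numeric", qLow = "numeric"))

setValidity("RoutingModel", function(object) {
  msg <- character()
  p <- c(object@passiveFidelity80, object@passiveFidelity60)
  if (any(p < 0 | p > 1)) msg <- c(msg, "passive fidelities must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RoutingModel", function(object) {
  cat("RoutingModel (logit): b0 =", signif(object@beta0, 6),
      "bV =", signif(object@betaV, 6), "bQ =", signif(object@betaQ, 6),
      "bVQ =", signif(object@betaVQ, 6), "bVol =", signif(object@betaVol, 6), "\n")
  cat("  passive fidelity:", object@passiveFidelity80, "@80 nL/s,",
      object@passiveFidelity60, "@60 nL/s | regimes: V_low =", object@vLow,
      "V_RMS, Q_low =", object@qLow, "nL/s\n")
})

# ---------------------------------------------------------------------------
# Statistics containers
# ---------------------------------------------------------------------------

#' Fitted binomial efficiency model
#'
#' Coefficients, standard errors and Wald p-values of the logit-link
#' binomial GLM over (V, Q, V:Q), with residual deviance, AIC (full
#' per-cell binomial likelihood convention), the number of grid cells and
#' a complete-separation flag.
#'
#' @slot coefficients named coefficient vector.
#' @slot se named standard errors.
#' @slot pvalues named Wald p-values.
#' @slot vcov variance-covariance matrix.
#' @slot deviance residual deviance.
#' @slot aic AIC.
#' @slot nobs number of grid cells.
#' @slot separation TRUE when (quasi-)complete separation was detected.
#' @export
setClass("EfficiencyModel", representation(
  coefficients = "numeric", se = "numeric", pvalues = "numeric",
  vcov = "matrix", deviance = "numeric", aic = "numeric", nobs = "integer",
  separation = "logical"))

setMethod("show", "EfficiencyModel", function(object) {
  cat("EfficiencyModel (binomial GLM, logit link),", object@nobs, "cells\n")
  tab <- data.frame(estimate = object@coefficients, se = object@se,
                    p = object@pvalues)
  print(signif(tab, 4))
  cat("deviance:", round(object@deviance, 2), "| AIC:", round(object@aic, 2),
      if (object@separation) "| WARNING: separation detected" else "", "\n")
})

#' Confusion matrix of a sort session
#'
#' @slot TP,FP,TN,FN counts.
#' @export
setClass("ConfusionMatrix", representation(
  TP = "integer", FP = "integer", TN = "integer", FN = "integer"))

setValidity("ConfusionMatrix", function(object) {
  if (any(c(object@TP, object@FP, object@TN, object@FN) < 0))
    "counts must be >= 0" else TRUE
})

#' @describeIn ConfusionMatrix constructor.
#' @param TP,FP,TN,FN counts.
#' @export
confusionMatrix <- function(TP, FP, TN, FN)
  new("ConfusionMatrix", TP = as.integer(TP), FP = as.integer(FP),
      TN = as.integer(TN), FN = as.integer(FN))

#' @rdname sensitivity
#' @export
setMethod("sensitivity", "ConfusionMatrix",
          function(x) x@TP / (x@TP + x@FN))

#' @rdname specificity
#' @export
setMethod("specificity", "ConfusionMatrix",
          function(x) x@TN / (x@TN + x@FP))

setMethod("show", "ConfusionMatrix", function(object) {
  m <- matrix(c(object@TP, object@FP, object@FN, object@TN), 2, 2,
              dimnames = list(truth = c("positive", "negative"),
                              routed = c("disfavored", "main")))
  print(m)
  cat("sensitivity:", sprintf("%.2f%%", 100 * sensitivity(object)),
      "| specificity:", sprintf("%.2f%%", 100 * specificity(object)), "\n")
})
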