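#' @include AllClasses.R
NULL

# lognormal parameterised by arithmetic mean and CV
.rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

.new_train <- function(df, config) {
  out <- new("DropletTrain", do.call(DataFrame, df))
  metadata(out)$config <- config
  out
}

# column replacement working around list-style `$<-` dispatch on DFrame
# subclasses: update the underlying DFrame, rewrap, keep metadata
.set_cols <- function(train, ...) {
  vals <- list(...)
  df <- as(train, "DFrame", strict = TRUE)
  for (nm in names(vals)) df[[nm]] <- vals[[nm]]
  out <- new(class(train), df)
  metadata(out) <- metadata(train)
  out
}

#' Simulate a droplet train
#'
#' Generates the ground truth of one screening session. Arrival times come
#' from the configured renewal process (default: Poisson with a dead time
#' at the transit scale, so plugs never overlap in the channel; pure
#' Poisson and strictly regular spacing are also available). Spore counts
#' are Poisson with mean \code{occupancyLambda}; volumes are lognormal at
#' the configured mean and CV; each occupied droplet draws a lognormal
#' wild-type fluorescein production rate, and a fraction of occupied
#' droplets carry a mutant clone whose rate is multiplied by a heavy-tailed
#' (lognormal, median 1) factor, producing the right-skewed activity
#' distribution seen in mutagenised libraries. The fluorescein
#' concentration at reinjection is filled in via
#' [incubationFluorescence()] and hyphal-exit times via
#' [hyphalExitProcess()]. Fully reproducible for a fixed seed.
#'
#' @param config a [SimConfig].
#' @return a [DropletTrain].
#' @examples
#' train <- simulateDropletTrain(simConfig(sessionLength = 30, seed = 7))
#' train
#' @export
simulateDropletTrain <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(config@seed)
  rate <- config@dropletRate
  len <- config@sessionLength
  mean_gap <- 1 / rate
  arrivals <- switch(config@arrivalMode,
    poisson = {
      n <- rpois(1, rate * len)
      sort(runif(n, 0, len))
    },
    regular = seq(mean_gap / 2, len, by = mean_gap),
    dead_time = {
      d <- min(config@minGap, 0.9 * mean_gap)
      n_max <- ceiling(rate * len * 1.5 + 10 * sqrt(rate * len))
      gaps <- d + rexp(n_max, rate = 1 / (mean_gap - d))
      tt <- cumsum(gaps)
      tt[tt <= len]
    })
  n <- length(arrivals)
  n_spores <- rpois(n, config@occupancyLambda)
  volume <- .rlnorm_mean_cv(n, config@dropletVolumeMean, config@volumeCV)
  occupied <- n_spores > 0
  activity <- numeric(n)
  activity[occupied] <- rlnorm(sum(occupied),
                               meanlog = log(config@activityMedian),
                               sdlog = config@activitySdlog)
  mutant <- logical(n)
  mutant[occupied] <- runif(sum(occupied)) < config@mutantFraction
  activity[mutant] <- activity[mutant] *
    rlnorm(sum(mutant), meanlog = 0, sdlog = config@mutantEffectSdlog)
  df <- list(
    id = seq_len(n), arrival_time = arrivals, volume = volume,
    n_spores = n_spores, mutant = mutant, activity_rate = activity,
    fluorescein_conc = rep(0, n), true_positive = rep(FALSE, n),
    hyphal_exit_time = rep(NA_real_, n),
    routed_channel = rep("unrouted", n), failure_mode = rep("none", n))
  train <- .new_train(df, config)
  train <- incubationFluorescence(train, config)
  hyphalExitProcess(train, config)
}

#' Fluorescein accumulation during incubation
#'
#' Linear substrate turnover: fluorescein = background + rate x time,
#' saturating at the in-droplet substrate concentration. Empty droplets
#' carry the substrate background only (spontaneous hydrolysis), which is
#' what makes them detectable -- and countable -- at the sorter.
#'
#' @param train a [DropletTrain] (or numeric activity rates, uM/h).
#' @param config a [SimConfig]; \code{incubationTime} must be >= 0.
#' @return the train with \code{fluorescein_conc} filled (uM), or a numeric
#'   vector when \code{train} is numeric.
#' @examples
#' incubationFluorescence(c(0, 1, 10),
#'   simConfig(incubationTime = 48, backgroundUM = 0.5))
#' @export
incubationFluorescence <- function(train, config) {
  if (config@incubationTime < 0) stop("incubation time must be >= 0")
  rates <- if (is(train, "DropletTrain")) train$activity_rate else train
  conc <- pmin(config@backgroundUM + rates * config@incubationTime,
               config@substrateCeilingUM)
  if (!is(train, "DropletTrain")) return(conc)
  .set_cols(train, fluorescein_conc = conc)
}

# media-dependent hyphal-exit kinetics: onset delay (h) before any exit is
# possible, then exponential time-to-exit. Calibrated qualitatively:
# glucose-only droplets exit from 24 h (bursting by ~48 h); colloidal
# chitin with low glucose or none delays exit past 96 h.
.exit_params <- function(media) {
  switch(media,
    G1      = list(onset = 24, mean = 18),
    CC1_G1  = list(onset = 48, mean = 36),
    CC1_G01 = list(onset = 96, mean = 48),
    CCMM    = list(onset = 96, mean = 48),
    MM      = list(onset = 96, mean = 72),
    stop("unknown media: ", media))
}

#' Hyphal-exit process
#'
#' Occupied droplets receive a time at which a hyphal tip first exits the
#' droplet: a media-dependent onset delay plus an exponential waiting time.
#' Empty droplets never exit. In glucose media exits begin at 24 h
#' post-incubation; with colloidal chitin and little or no glucose no exit
#' occurs before 96 h.
#'
#' @param train a [DropletTrain].
#' @param config a [SimConfig]; \code{media} selects the kinetics.
#' @return the train with \code{hyphal_exit_time} filled (h; NA = no exit).
#' @export
hyphalExitProcess <- function(train, config) {
  par <- .exit_params(config@media)
  occupied <- which(train$n_spores > 0)
  exit <- rep(NA_real_, nrow(train))
  if (length(occupied))
    exit[occupied] <- par$onset + rexp(length(occupied), rate = 1 / par$mean)
  .set_cols(train, hyphal_exit_time = exit)
}

#' Mark ground-truth positives
#'
#' Sets \code{true_positive} to droplets whose reinjection fluorescein
#' concentration exceeds a threshold (uM) -- the "above-gate by
#' construction" class used for scoring.
#'
#' @param train a [DropletTrain].
#' @param thresholdUM threshold in uM.
#' @return the updated train.
#' @export
markPositives <- function(train, thresholdUM) {
  .set_cols(train, true_positive = train$fluorescein_conc > thresholdUM)
}

#' Simulate a mixed positive/negative calibration train
#'
#' The two-population sorter-calibration design: fluorescein standard
#' droplets (positives, at \code{posUM}) mixed with dye-only droplets
#' carrying no fluorescein (negatives). Arrival process and seed semantics
#' as in [simulateDropletTrain()].
#'
#' @param n number of droplets.
#' @param posFraction fraction of positives.
#' @param posUM fluorescein concentration of positives, uM.
#' @param negUM fluorescein-equivalent concentration of negatives, uM.
#' @param rate droplet rate, events/s.
#' @param arrivalMode arrival process (see [simConfig()]).
#' @param seed integer seed.
#' @return a [DropletTrain] with \code{true_positive} set.
#' @export
simulateMixedTrain <- function(n, posFraction = 0.1, posUM = 5, negUM = 0,
                               rate = 7, arrivalMode = "regular", seed = 1L) {
  config <- simConfig(dropletRate = rate, sessionLength = (n + 1) / rate,
                      occupancyLambda = 0, mutantFraction = 0,
                      arrivalMode = arrivalMode, seed = seed,
                      backgroundUM = negUM)
  set.seed(seed)
  gap <- 1 / rate
  arrivals <- switch(arrivalMode,
    regular = seq(gap / 2, by = gap, length.out = n),
    poisson = sort(runif(n, 0, n * gap)),
    dead_time = {
      d <- min(config@minGap, 0.9 * gap)
      cumsum(d + rexp(n, rate = 1 / (gap - d)))
    })
  positive <- runif(n) < posFraction
  df <- list(
    id = seq_len(n), arrival_time = arrivals,
    volume = .rlnorm_mean_cv(n, 1, 0.05), n_spores = rep(0L, n),
    mutant = rep(FALSE, n), activity_rate = rep(0, n),
    fluorescein_conc = ifelse(positive, posUM, negUM),
    true_positive = positive, hyphal_exit_time = rep(NA_real_, n),
    routed_channel = rep("unrouted", n), failure_mode = rep("none", n))
  .new_train(df, config)
}

#' Synthesise a spectrometer frame stream
#'
#' Emulates the acquisition the controller consumes. Baseline frames hold
#' the dark spectrum plus Gaussian read noise; during each droplet transit
#' (a rectangular pulse of the configured duration) a Gaussian emission
#' band centred at the fluorescein emission wavelength is added with peak
#' amplitude \code{gainRFUperUM x fluorescein_conc}. Frames are strictly
#' time-ordered and the stream is bitwise reproducible for a fixed seed.
#'
#' @param train a [DropletTrain], sorted by arrival time.
#' @param detector a [DetectorModel].
#' @param transitTime droplet transit duration, s.
#' @param tRange time window to synthesise, s (default: the whole session).
#' @param seed integer seed for the read noise.
#' @return a [SpectralFrames] object.
#' @export
synthesizeFrames <- function(train, detector, transitTime = 0.04,
                             tRange = NULL, seed = 1L) {
  raw <- .synth_matrix(train, detector, transitTime, tRange, seed)
  SpectralFrames(raw$mat, detector@wavelengthGrid, raw$times)
}

# raw matrix + time grid synthesis (shared by synthesizeFrames and the
# chunked session runner, which skips the container for speed)
.synth_matrix <- function(train, detector, transitTime = 0.04,
                          tRange = NULL, seed = 1L) {
  stopifnot(is(detector, "DetectorModel"))
  if (is.unsorted(train$arrival_time)) stop("train must be sorted by arrival_time")
  if (is.null(tRange)) {
    cfg <- metadata(train)$config
    tmax <- if (!is.null(cfg)) cfg@sessionLength else
      max(train$arrival_time, 0) + 2 * transitTime
    tRange <- c(0, tmax)
  }
  dt <- detector@framePeriod
  times <- seq(tRange[1], tRange[2], by = dt)
  wl <- detector@wavelengthGrid
  W <- length(wl); T <- length(times)
  set.seed(seed)
  mat <- matrix(rnorm(W * T, sd = detector@noiseSD), nrow = W) +
    detector@darkSpectrum
  band <- exp(-0.5 * ((wl - detector@emissionCenter) /
                        detector@emissionWidthSD)^2)
  sel <- which(train$arrival_time < tRange[2] &
                 train$arrival_time + transitTime > tRange[1])
  if (length(sel)) {
    t0 <- train$arrival_time[sel]
    eps <- 1e-9
    from <- ceiling((t0 - tRange[1]) / dt - eps) + 1L
    to <- floor((t0 + transitTime - tRange[1]) / dt + eps) + 1L
    amp <- detector@gainRFUperUM * train$fluorescein_conc[sel]
    .addTransitsCpp(mat, band, as.integer(from), as.integer(to), amp)
  }
  list(mat = mat, times = times)
}
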