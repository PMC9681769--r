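#' @include AllClasses.R
NULL

# chunked full-chain detection: synthesize + process the stream in windows
# whose boundaries fall in the middle of cold gaps, so no transit is ever
# split across chunks. Returns the per-frame peak table for the session.
.detect_stream <- function(train, detector, settings, criteria,
                           transitTime, chunkLength = 200, seed = 1L) {
  cfg <- metadata(train)$config
  total <- if (!is.null(cfg)) cfg@sessionLength else
    max(train$arrival_time) + 2 * transitTime
  arr <- train$arrival_time
  dt <- detector@framePeriod
  bounds <- 0
  target <- chunkLength
  while (target < total) {
    # cut in the middle of the nearest cold gap, snapped onto the global
    # frame grid so every chunk samples the same instants
    i <- findInterval(target, arr)
    lo <- if (i >= 1) arr[i] + transitTime else 0
    hi <- if (i < length(arr)) arr[i + 1] else total
    bounds <- c(bounds, min(round((lo + hi) / 2 / dt) * dt, total))
    target <- target + chunkLength
  }
  bounds <- c(bounds, total)
  co <- .butter_coefs(settings)
  out <- vector("list", length(bounds) - 1)
  for (k in seq_along(out)) {
    raw <- .synth_matrix(train, detector, transitTime = transitTime,
                         tRange = c(bounds[k], bounds[k + 1]),
                         seed = seed + k)
    out[[k]] <- .processStreamCpp(raw$mat, detector@darkSpectrum, raw$times,
                                  detector@wavelengthGrid, co$b, co$a,
                                  criteria@minHeight, criteria@minProminence,
                                  criteria@minBaseWidth, criteria@minDistance,
                                  prescreen = criteria@minHeight)
  }
  res <- do.call(rbind, out)
  res[order(res$time), , drop = FALSE]
}

#' Detect droplet events over a whole session
#'
#' Convenience wrapper running the full detection chain -- stream
#' synthesis, background subtraction, denoising, per-frame peak detection
#' and event segmentation -- over a droplet train, in memory-bounded
#' chunks cut in the middle of inter-droplet gaps.
#'
#' @param train a [DropletTrain].
#' @param detector a [DetectorModel].
#' @param settings a [FilterSettings].
#' @param criteria a [PeakCriteria].
#' @param transitTime droplet transit duration, s.
#' @param refractory event-merge interval, s.
#' @param seed integer seed for the detector noise.
#' @return event table as from [segmentEvents()].
#' @export
detectSessionEvents <- function(train, detector = detectorModel(),
                                settings = filterSettings(),
                                criteria = peakCriteria(),
                                transitTime = 0.04, refractory = 0.05,
                                seed = 1L) {
  peaks <- .detect_stream(train, detector, settings, criteria,
                          transitTime, seed = seed)
  segmentEvents(peaks, refractory = refractory)
}

#' Run a closed-loop sorting session
#'
#' End-to-end simulation of one autonomous sort: the droplet train is
#' rendered into spectrometer frames, processed into gated events, fed to
#' the pulse-scheduling controller, and every droplet is routed through
#' the stochastic Y-junction model. A pulse actually captures its droplet
#' only when it starts within the capture window around the droplet's
#' passage of the pulsing electrode (arrival + travel time + half a
#' transit); otherwise the droplet routes passively -- this is how timing
#' jitter degrades sensitivity while leaving specificity untouched.
#'
#' @param train a [DropletTrain] with \code{true_positive} set.
#' @param g a [Gate].
#' @param detector a [DetectorModel].
#' @param settings a [FilterSettings].
#' @param criteria a [PeakCriteria].
#' @param timing a [TimingModel]; its oil flow is also the routing flow.
#' @param pulse a [PulseSettings]; its amplitude is the routing potential.
#' @param model a [RoutingModel].
#' @param transitTime droplet transit duration, s.
#' @param refractory event-merge interval, s.
#' @param latency deterministic detection latency, s.
#' @param jitterSD Gaussian latency jitter sd, s (0 = perfect timing).
#' @param captureWindow half-width of the electrode capture window, s.
#' @param seed integer seed (noise, jitter and routing substreams are
#'   derived from it).
#' @return list with \code{train} (routed), \code{events}, \code{log}
#'   (a [SortLog]) and \code{confusion} (a [ConfusionMatrix]).
#' @export
runClosedLoop <- function(train, g, detector = detectorModel(),
                          settings = filterSettings(),
                          criteria = peakCriteria(),
                          timing = timingModel(oilFlow = 80),
                          pulse = pulseSettings(amplitude = 44.2),
                          model = dropletRoutingModel(),
                          transitTime = 0.04, refractory = 0.05,
                          latency = 0.010, jitterSD = 0.010,
                          captureWindow = 0.015, seed = 1L) {
  events <- detectSessionEvents(train, detector, settings, criteria,
                                transitTime, refractory, seed = seed)
  # schedule on first-frame detection (the live system fires on the first
  # gated frame, not after the transit completes)
  sched <- events
  sched$peak_time <- sched$start_time
  log <- runController(sched, g, timing, pulse, latency = latency,
                       jitterSD = jitterSD, seed = seed + 1L)
  idx <- matchEventsToTrain(events, train, transitTime = transitTime)
  tau <- travelTime(timing)
  pulsed <- logical(nrow(train))
  firing <- which(log$pulse_issued & !is.na(idx))
  if (length(firing)) {
    d <- idx[firing]
    t_pe <- train$arrival_time[d] + transitTime / 2 + tau
    captured <- abs(log$pulse_start[firing] - t_pe) <= captureWindow
    pulsed[d[captured]] <- TRUE
  }
  routed <- routeDroplets(train, pulsed = pulsed, V = pulse@amplitude,
                          Q = timing@oilFlow, model = model,
                          pulseDuration = pulse@duration, seed = seed + 2L)
  list(train = routed, events = events, log = log,
       confusion = scoreSession(routed))
}
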