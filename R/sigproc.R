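#' @include AllClasses.R
NULL

#' Background subtraction
#'
#' Removes excitation noise and background light from a raw spectrum. Two
#' modes are available. \code{"plain"} (the default used by the processing
#' chain) returns \code{|I_n - I_dark|}, a stationary baseline suitable for
#' peak detection. \code{"accumulate"} applies the running recurrence
#' \code{I = |I_{n-1} + (I_n - I_dark)|} element-wise, carrying the previous
#' output spectrum forward; it integrates any sustained signal without
#' bound and is provided for parity with live-display pipelines that reset
#' between droplets.
#'
#' @param spectrum raw intensities on the detector grid, RFU.
#' @param dark dark spectrum on the same grid, RFU.
#' @param previous previous output spectrum (\code{accumulate} mode); use a
#'   zero spectrum for the first frame.
#' @param mode \code{"plain"} or \code{"accumulate"}.
#' @return non-negative background-subtracted spectrum, RFU.
#' @examples
#' subtractBackground(100, 40, previous = 0, mode = "accumulate")  # 60
#' subtractBackground(90, 40, previous = 60, mode = "accumulate")  # 110
#' @export
subtractBackground <- function(spectrum, dark, previous = NULL,
                               mode = c("plain", "accumulate")) {
  mode <- match.arg(mode)
  if (length(spectrum) != length(dark))
    stop("spectrum and dark spectrum are on different grids (",
         length(spectrum), " vs ", length(dark), " channels)")
  if (mode == "plain") return(abs(spectrum - dark))
  if (is.null(previous))
    stop("mode 'accumulate' requires the previous spectrum (zero for the first frame)")
  if (length(previous) != length(spectrum))
    stop("previous spectrum is on a different grid")
  abs(previous + (spectrum - dark))
}

.butter_coefs <- function(settings) {
  bf <- signal::butter(settings@order, settings@cutoff, type = "low")
  list(b = bf$b, a = bf$a)
}

#' Butterworth denoising
#'
#' Single-pass causal lowpass along the wavelength axis (third order, 0.1
#' normalised cutoff by default). DC gain is 1, so broad emission bands
#' pass essentially unattenuated while channel-to-channel read noise is
#' suppressed. Zero-phase (forward-backward) filtering is deliberately not
#' used: the chain mirrors a real-time system.
#'
#' @param spectrum numeric vector of intensities.
#' @param settings a [FilterSettings].
#' @return filtered spectrum of the same length.
#' @export
denoiseSpectrum <- function(spectrum, settings = filterSettings()) {
  stopifnot(is(settings, "FilterSettings"))
  if (length(spectrum) <= 3 * settings@order)
    stop("spectrum too short for filter order ", settings@order)
  co <- .butter_coefs(settings)
  .iirFilterCpp(as.numeric(spectrum), co$b, co$a)
}

#' Detect spectral peaks
#'
#' Topographic peak detection on a single spectrum: local maxima filtered
#' by the four criteria -- height, base width, separation from neighbouring
#' retained peaks, and prominence (height above the lowest contour line
#' separating the peak from a higher one; side bases are the minima on the
#' walks to the nearest higher sample or the spectrum edge).
#'
#' @param spectrum numeric intensities, RFU.
#' @param wavelength wavelength grid, nm (same length).
#' @param criteria a [PeakCriteria].
#' @param frameTime optional acquisition time attached to the result, s.
#' @return \code{data.frame} with columns \code{frame_time, wavelength,
#'   intensity, prominence, base_width}, sorted by wavelength (zero rows
#'   when nothing qualifies).
#' @export
detectPeaks <- function(spectrum, wavelength, criteria = peakCriteria(),
                        frameTime = NA_real_) {
  stopifnot(is(criteria, "PeakCriteria"))
  if (length(spectrum) != length(wavelength))
    stop("spectrum and wavelength grid differ in length")
  pk <- .findPeaksCpp(as.numeric(spectrum), as.numeric(wavelength),
                      criteria@minHeight, criteria@minProminence,
                      criteria@minBaseWidth, criteria@minDistance)
  data.frame(frame_time = rep(frameTime, nrow(pk)),
             wavelength = pk$wavelength, intensity = pk$intensity,
             prominence = pk$prominence, base_width = pk$base_width)
}

#' Run the full per-frame processing chain over a stream
#'
#' For every frame: plain background subtraction against the detector dark
#' spectrum, causal Butterworth denoising along the wavelength axis, and
#' peak detection. Frames whose raw background-subtracted maximum cannot
#' reach the height criterion are skipped, which makes 30-minute sessions
#' tractable without changing the result.
#'
#' @param frames a [SpectralFrames] stream.
#' @param dark dark spectrum, RFU (default: zeros -- pass
#'   \code{detector@darkSpectrum} for simulated streams).
#' @param settings a [FilterSettings].
#' @param criteria a [PeakCriteria].
#' @return \code{data.frame} of per-frame peaks: \code{frame, time,
#'   wavelength, intensity, prominence, base_width}.
#' @export
processFrames <- function(frames, dark = NULL,
                          settings = filterSettings(),
                          criteria = peakCriteria()) {
  stopifnot(is(frames, "SpectralFrames"))
  mat <- intensityMatrix(frames)
  if (is.null(dark)) dark <- numeric(nrow(mat))
  if (length(dark) != nrow(mat))
    stop("dark spectrum does not match the stream's wavelength grid")
  co <- .butter_coefs(settings)
  .processStreamCpp(mat, dark, frameTimes(frames), wavelengths(frames),
                    co$b, co$a, criteria@minHeight, criteria@minProminence,
                    criteria@minBaseWidth, criteria@minDistance,
                    prescreen = criteria@minHeight)
}

#' Segment per-frame peaks into droplet events
#'
#' Consecutive frames carrying peaks merge into one droplet event whenever
#' their times are closer than the refractory interval; the event peak is
#' the maximum-intensity frame peak. With transits separated by more than
#' the refractory interval, the event count equals the droplet count.
#'
#' @param peaks per-frame peak table from [processFrames()] (time-ordered).
#' @param refractory merge interval, s.
#' @return \code{data.frame} of events: \code{event_id, start_time,
#'   end_time, peak_time, wavelength, intensity, prominence, base_width,
#'   n_frames, gated}.
#' @export
segmentEvents <- function(peaks, refractory = 0.05) {
  if (nrow(peaks) == 0)
    return(data.frame(event_id = integer(), start_time = numeric(),
                      end_time = numeric(), peak_time = numeric(),
                      wavelength = numeric(), intensity = numeric(),
                      prominence = numeric(), base_width = numeric(),
                      n_frames = integer(), gated = logical()))
  if (is.unsorted(peaks$time)) stop("peak table must be time-ordered")
  ft <- sort(unique(peaks$time))
  ev_of_frame <- cumsum(c(TRUE, diff(ft) >= refractory))
  ev <- ev_of_frame[match(peaks$time, ft)]
  # vectorised per-event aggregation: events arrive time-ordered, so group
  # ids are already sorted; the best row per event is the first after
  # ordering by (event, -intensity)
  o <- order(ev, -peaks$intensity)
  best <- o[!duplicated(ev[o])]
  tsplit <- split(peaks$time, ev)
  out <- data.frame(
    event_id = seq_along(best),
    start_time = vapply(tsplit, min, 0),
    end_time = vapply(tsplit, max, 0),
    peak_time = peaks$time[best], wavelength = peaks$wavelength[best],
    intensity = peaks$intensity[best], prominence = peaks$prominence[best],
    base_width = peaks$base_width[best],
    n_frames = vapply(tsplit, function(x) length(unique(x)), 0L),
    gated = FALSE, row.names = NULL)
  out
}

#' Apply a gate to droplet events
#'
#' A pure, idempotent flagging operation: an event is gated when its peak
#' wavelength lies in the closed gate window, its peak intensity lies in
#' the closed intensity window, and the intensity is strictly above the
#' noise level.
#'
#' @param events event table from [segmentEvents()].
#' @param g a [Gate].
#' @return the events with the \code{gated} column set.
#' @export
applyGate <- function(events, g) {
  stopifnot(is(g, "Gate"))
  if (nrow(events) == 0) return(events)
  events$gated <- events$wavelength >= g@wavelengthMin &
    events$wavelength <= g@wavelengthMax &
    events$intensity >= g@intensityMin &
    events$intensity <= g@intensityMax &
    events$intensity > g@noiseLevel
  events
}

#' Build an intensity gate at a population quantile
#'
#' The screening gate: the intensity threshold is the empirical
#' \code{q}-quantile of the measured peak intensities (linear interpolation
#' between order statistics, the common type-7 rule), the upper bound is
#' open, and the wavelength window defaults to 510-520 nm. With q = 0.9 the
#' top ~10% of droplets pass.
#'
#' @param intensities measured peak intensities, RFU (>= 2 values).
#' @param q quantile in (0, 1).
#' @param window wavelength window, nm.
#' @param noiseLevel noise floor, RFU.
#' @return a [Gate].
#' @examples
#' quantileGate(1:10, 0.9)  # threshold 9.1
#' @export
quantileGate <- function(intensities, q = 0.9, window = c(510, 520),
                         noiseLevel = 0) {
  if (length(intensities) < 2) stop("need at least 2 intensities")
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  thr <- unname(quantile(intensities, q, type = 7))
  gate(wavelengthMin = window[1], wavelengthMax = window[2],
       intensityMin = max(thr, noiseLevel), intensityMax = Inf,
       noiseLevel = noiseLevel)
}

#' Gate-window presets
#'
#' \code{"default"}: the 510-520 nm gating window; \code{"wide"}: the
#' 500-520 nm window.
#'
#' @param name preset name.
#' @return numeric wavelength window, nm.
#' @export
gatePreset <- function(name = c("default", "wide")) {
  switch(match.arg(name), default = c(510, 520), wide = c(500, 520))
}

#' Histogram and summary of event peak intensities
#'
#' The gating-histogram view: counts per intensity bin plus the summary
#' used when setting a gate (event count N and intensity quantiles).
#'
#' @param events event table (>= 1 row).
#' @param breaks passed to [graphics::hist()] interface-compatible binning
#'   via [base::cut()]; either a bin count or a vector of break points.
#' @param probs quantiles to report.
#' @return list with \code{counts}, \code{breaks}, \code{mids}, \code{n},
#'   \code{quantiles}.
#' @export
peakHistogram <- function(events, breaks = 30,
                          probs = c(0.1, 0.25, 0.5, 0.75, 0.9)) {
  if (nrow(events) == 0) stop("no events to histogram")
  x <- events$intensity
  if (length(breaks) == 1) {
    rng <- range(x)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1], rng[2], length.out = breaks + 1)
  }
  cnt <- as.integer(table(cut(x, breaks, include.lowest = TRUE)))
  list(counts = cnt, breaks = breaks,
       mids = (head(breaks, -1) + breaks[-1]) / 2, n = length(x),
       quantiles = quantile(x, probs, type = 7))
}
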