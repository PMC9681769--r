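#' @include AllClasses.R
NULL

#' Droplet travel time
#'
#' Delay between optical detection and arrival at the sorting junction,
#' modelled as tau = k / Q. With the default k = 3 nL this reproduces the
#' 0.1 s travel time at a total oil flow of 30 nL/s, and halves whenever
#' the flow doubles.
#'
#' @param timing a [TimingModel].
#' @return travel time, s.
#' @examples
#' travelTime(timingModel(oilFlow = 30))  # 0.1 s
#' @export
travelTime <- function(timing) {
  stopifnot(is(timing, "TimingModel"))
  validObject(timing)
  timing@travelConstant / timing@oilFlow
}

#' Run the autonomous sorting controller
#'
#' Watches a time-ordered event stream, applies the gate, and schedules a
#' pulsing-electrode actuation for every gated event at
#' \code{detect_time + latency + tau}. The electrode cannot double-fire: if
#' a gated event arrives while a pulse is still active, no new pulse is
#' issued and the event is flagged \code{merge_risk} (the droplet may merge
#' with the droplet being sorted). Detection latency is one frame period
#' plus optional Gaussian jitter, the mechanism by which imperfect
#' travel-time knowledge degrades sensitivity.
#'
#' @param events event table from [segmentEvents()] (time-ordered).
#' @param g a [Gate].
#' @param timing a [TimingModel].
#' @param pulse a [PulseSettings].
#' @param latency deterministic detection latency, s (default one 10 ms
#'   frame period).
#' @param jitterSD standard deviation of Gaussian latency jitter, s.
#' @param seed integer seed for the jitter draws.
#' @return a [SortLog] with one record per event; \code{metadata()} holds
#'   session counters and the travel time used.
#' @export
runController <- function(events, g, timing = timingModel(),
                          pulse = pulseSettings(), latency = 0.010,
                          jitterSD = 0, seed = 1L) {
  stopifnot(is(g, "Gate"), is(pulse, "PulseSettings"))
  n <- nrow(events)
  if (n > 1 && is.unsorted(events$peak_time)) stop("events must be time-ordered")
  events <- applyGate(events, g)
  tau <- travelTime(timing)
  set.seed(seed)
  jit <- if (jitterSD > 0) rnorm(n, 0, jitterSD) else numeric(n)
  pulse_issued <- logical(n)
  pulse_start <- rep(NA_real_, n)
  merge_risk <- logical(n)
  busy_until <- -Inf
  for (i in seq_len(n)) {
    if (!events$gated[i]) next
    decision <- events$peak_time[i] + latency + jit[i]
    if (decision < busy_until) {
      merge_risk[i] <- TRUE
      next
    }
    pulse_issued[i] <- TRUE
    pulse_start[i] <- decision + tau
    busy_until <- pulse_start[i] + pulse@duration
  }
  log <- new("SortLog", DataFrame(
    event_id = events$event_id, detect_time = events$peak_time,
    gated = events$gated, pulse_issued = pulse_issued,
    pulse_start = pulse_start, merge_risk = merge_risk))
  metadata(log)$travel_time <- tau
  metadata(log)$pulse_duration <- pulse@duration
  metadata(log)$latency <- latency
  metadata(log)$jitterSD <- jitterSD
  metadata(log)$counters <- c(events = n, gated = sum(events$gated),
                              pulses = sum(pulse_issued),
                              merge_risk = sum(merge_risk))
  log
}

#' Match detected events to ground-truth droplets
#'
#' Associates each event with the droplet whose transit window contains
#' the event peak time (nearest arrival not later than the peak, within
#' one transit plus one frame period).
#'
#' @param events event table.
#' @param train a [DropletTrain].
#' @param transitTime transit duration used in synthesis, s.
#' @param slack extra tolerance, s.
#' @return integer vector: for each event, the matched droplet row (NA when
#'   unmatched).
#' @export
matchEventsToTrain <- function(events, train, transitTime = 0.04,
                               slack = 0.011) {
  arr <- train$arrival_time
  eps <- 1e-6  # frame times may sit a rounding error before the arrival
  idx <- findInterval(events$peak_time + eps, arr)
  idx[idx == 0] <- NA_integer_
  ok <- !is.na(idx) &
    events$peak_time <= arr[pmax(idx, 1)] + transitTime + slack
  idx[!ok] <- NA_integer_
  idx
}

#' Score a sort session against ground truth
#'
#' Tallies the confusion matrix by comparing each droplet's routed channel
#' with its true class: a positive droplet counts as a true positive when
#' it was routed to the disfavored (collection) channel, a negative as a
#' true negative when it was not. The matrix marginals equal the droplet
#' count.
#'
#' @param train a routed [DropletTrain] (after [runClosedLoop()] or
#'   [routeDroplets()]).
#' @return a [ConfusionMatrix].
#' @export
scoreSession <- function(train) {
  pos <- train$true_positive
  sorted <- train$routed_channel == "disfavored"
  confusionMatrix(TP = sum(pos & sorted), FP = sum(!pos & sorted),
                  TN = sum(!pos & !sorted), FN = sum(pos & !sorted))
}
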