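# shared in-code fixtures

# Gaussian emission bump over a flat baseline on the default 450-650 grid
gaussian_spectrum <- function(center = 515, amplitude = 1000, sd = 10,
                              baseline = 0, wl = seq(450, 650, by = 0.5)) {
  list(wl = wl, y = baseline + amplitude * exp(-0.5 * ((wl - center) / sd)^2))
}

# minimal droplet train straight from column values (defaults recycled)
make_train <- function(n, arrival_time = seq_len(n) / 7, volume = 1,
                       n_spores = 0L, activity_rate = 0,
                       fluorescein_conc = 0, true_positive = FALSE,
                       routed_channel = "unrouted", failure_mode = "none") {
  df <- S4Vectors::DataFrame(
    id = seq_len(n), arrival_time = arrival_time,
    volume = rep_len(volume, n), n_spores = rep_len(as.integer(n_spores), n),
    mutant = rep_len(FALSE, n), activity_rate = rep_len(activity_rate, n),
    fluorescein_conc = rep_len(fluorescein_conc, n),
    true_positive = rep_len(true_positive, n),
    hyphal_exit_time = rep_len(NA_real_, n),
    routed_channel = rep_len(routed_channel, n),
    failure_mode = rep_len(failure_mode, n))
  new("DropletTrain", df)
}

# hand-built per-frame peak table (one peak per listed frame time)
make_peaks <- function(times, wavelength = 515, intensity = 1000) {
  n <- length(times)
  data.frame(frame = seq_len(n), time = times,
             wavelength = rep_len(wavelength, n),
             intensity = rep_len(intensity, n),
             prominence = rep_len(intensity, n),
             base_width = rep_len(50, n))
}

# hand-built event table for controller tests
make_events <- function(times, wavelength = 515, intensity = 1000) {
  n <- length(times)
  data.frame(event_id = seq_len(n), start_time = times, end_time = times,
             peak_time = times, wavelength = rep_len(wavelength, n),
             intensity = rep_len(intensity, n),
             prominence = rep_len(intensity, n),
             base_width = rep_len(50, n),
             n_frames = rep_len(1L, n), gated = rep_len(FALSE, n))
}

# steady-state amplitude of a filtered unit sinusoid at a normalised
# frequency (Nyquist = 1), measured by RMS over the tail
filtered_amplitude <- function(normfreq, settings = filterSettings(),
                               n = 4000) {
  x <- sin(pi * normfreq * seq_len(n))
  y <- denoiseSpectrum(x, settings)
  sqrt(2 * mean(y[(n / 2 + 1):n]^2))
}

# analytic magnitude of the digital (bilinear) Butterworth lowpass
digital_butter_gain <- function(normfreq, cutoff = 0.1, order = 3) {
  1 / sqrt(1 + (tan(pi * normfreq / 2) / tan(pi * cutoff / 2))^(2 * order))
}
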