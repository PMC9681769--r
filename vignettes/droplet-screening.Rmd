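---
title: "Models and methods behind dropScreen"
author: "dropScreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dropScreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropScreen)
```

# Overview

`dropScreen` is the computational core of a fluorescence-activated droplet
sorting (FADS) platform for filamentous fungi. Single spores are
encapsulated with a fluorogenic glycoside-hydrolase substrate in ~1 nL
water-in-oil droplets, incubated for days on a colloidal-chitin solid
support, reinjected past a fibre-coupled spectrometer, and diverted by a
low-voltage pulsed electrode when their fluorescein emission passes a gate.
The package simulates the droplet stream and detector, implements the
real-time spectral processing and sort-control logic, models the
electrostatic Y-junction outcome, and provides the screening statistics.
Everything is seeded and deterministic, so the whole control chain can be
exercised and scored against ground truth without hardware.

# The droplet-stream simulator

## Encapsulation and arrivals

Spore occupancy per droplet is Poisson with mean
$\lambda = c \cdot V$ (concentration times droplet volume); the default
$\lambda = 0.35$ corresponds to $0.35\times10^6$ spores/mL in 1 nL
droplets, giving $P(\ge 1) = 1-e^{-0.35} \approx 29.5\%$ occupied droplets
and a mostly-single-spore occupied population.

Arrival times at the detector are a renewal process at 7 droplets/s. The
default mode (`"dead_time"`) draws inter-arrival gaps as a fixed dead time
(0.1 s) plus an exponential excess, keeping the mean gap exactly $1/$rate.
The dead time reflects the physics of a droplet train: droplets are
incompressible plugs generated at a clocked junction and cannot overlap at
the detection spot. A homogeneous Poisson process (no dead time) and a
strictly regular train are available as options; with pure Poisson
arrivals at 7 Hz roughly a quarter of consecutive transits overlap within
a 40 ms transit window, which no gap-based event segmentation can
disentangle — that regime is useful for stress-testing, not for emulating
a physical train.

## Fluorescence during incubation

Each occupied droplet draws a clone activity (fluorescein production rate,
µM/h) from a lognormal distribution; a configurable fraction of occupied
droplets are "mutants" whose rate is multiplied by a second lognormal
factor with median 1. The product of two lognormals is right-skewed, which
reproduces the right-skewed mutant-library intensity histograms that
motivate the 0.9-quantile sorting gate. Fluorescein accumulates linearly
in time and saturates at the in-droplet substrate concentration
(100 µM default). Empty droplets carry only the substrate background
(default 5 µM fluorescein-equivalent). The background matters: a screening
session counts *all* droplets, including empties, from their background
fluorescence, so the background must sit comfortably above detector noise.
With the default detector gain (20 RFU/µM) and read noise (3 RFU), an
empty droplet peaks at ~100 RFU against a ~1 RFU filtered noise floor.

## Hyphal exit

Occupied droplets receive a time-to-hyphal-exit: a media-dependent onset
delay plus an exponential waiting time. Defaults encode the qualitative
anchors of solid-state droplet fermentation: with 1% glucose alone exits
begin at 24 h (and droplets burst by ~48 h); with 1% colloidal chitin and
0.1% or no glucose, no exit occurs before 96 h. The onset/mean pairs per
media are design parameters, not fitted values — only their ordering and
the 24 h / 96 h onsets are anchored.

## The synthetic detector

Frames are generated on a 450–650 nm grid at 0.5 nm every 10 ms: a dark
spectrum (flat offset plus a 470 nm excitation bleed-through band),
Gaussian read noise, and — during each 40 ms droplet transit — a Gaussian
fluorescein emission band centred at 515 nm (sd 15 nm) with peak amplitude
proportional to the droplet's fluorescein concentration. Transits are
rectangular in time; smooth entry/exit ramps would not change the peak
logic, which keys on the per-frame spectrum. The spectrometer integration
time is not a printed quantity; 10 ms is the package's stand-in and is a
configuration field.

What the simulator does *not* emulate: droplet shrinkage or swelling
during incubation beyond a volume CV, spectral cross-talk between
neighbouring droplets, photobleaching, and baseline drift. Passing tests
therefore demonstrate correctness of the processing and control logic
under the stated noise model, not robustness to every real-instrument
artefact.

# The spectral processing chain

Each frame passes through:

1. **Background subtraction.** The default (`"plain"`) mode is
   $|I_n - I_{\mathrm{dark}}|$, which keeps the baseline stationary. The
   running recurrence $I = |I_{n-1} + (I_n - I_{\mathrm{dark}})|$ is also
   provided (`"accumulate"`); applied literally it integrates any
   sustained signal without bound, so it is not the default — peak
   detection needs a stationary baseline, and no reset rule is assumed.
2. **Denoising.** A third-order digital Butterworth lowpass at 0.1
   normalised cutoff, applied causally along the wavelength axis (the
   live system filters each acquired spectrum as it arrives; zero-phase
   forward–backward filtering would be anticausal). Its DC gain is 1 and
   its magnitude at the cutoff is exactly $1/\sqrt{2}$ by bilinear
   prewarping. Away from the cutoff the digital response follows the
   warped analytic form
   $1/\sqrt{1+(\tan(\pi f/2)/\tan(\pi f_c/2))^{2n}}$ — at $4f_c$ this is
   0.0104, noticeably below the analog-prototype value 0.0156; the tests
   assert the warped (true) response.
3. **Peak detection.** Local maxima filtered by the four classical
   criteria: height, base width, separation from neighbouring retained
   peaks, and topographic prominence (height above the lowest contour
   separating the peak from a higher one). Ties on plateaus take the
   plateau midpoint; when two candidates violate the separation rule the
   taller wins.
4. **Event segmentation.** Frames carrying peaks merge into one droplet
   event when their times are closer than a refractory interval (default
   50 ms, chosen between the 10 ms frame spacing within a transit and the
   ≥60 ms cold gap between dead-time arrivals at 7 Hz). The event peak is
   the maximum-intensity frame peak.
5. **Gating.** An event is gated when its peak wavelength lies in the
   closed gate window, its intensity in the closed intensity window, and
   strictly above the noise floor. The default window is 510–520 nm; a
   wider 500–520 nm preset ships as `gatePreset("wide")`. Screening gates
   are set at the 0.9 empirical quantile (type-7 linear interpolation) of
   the measured population, passing the top ~10%.

Causal filtering shifts peaks by the filter group delay (~1–2 nm on the
0.5 nm grid); the default gate window comfortably absorbs this.

# The sort controller

For each gated event the controller schedules a pulsing-electrode
actuation at `detect + latency + tau`, where the travel time
$\tau = k/Q$ is calibrated once from the printed anchor (0.1 s at a total
oil flow of 30 nL/s, so $k = 3$ nL). The pulse is 300 ms of 10 kHz sine;
while a pulse is active no new pulse can be issued and a gated arrival is
flagged `merge_risk` — the refractory equals the pulse duration because a
live electrode cannot double-fire. This implies an actuation ceiling of
~3.3 Hz against 7 Hz detection, acceptable because gated positives are
~10% of events.

Detection latency is one frame period plus Gaussian jitter (sd 10 ms by
default). A pulse only captures its droplet when it starts within a
capture window (±15 ms) around the droplet's passage of the electrode;
that window is the time a droplet spends in front of the electrode gap,
about half a transit. With zero jitter the schedule always lands inside
the window (100% sensitivity); with the default jitter a predictable
fraction of pulses miss, reproducing the sub-100% sensitivity of
experimentally timed actuation while leaving specificity untouched
(negatives are never pulsed).

# The electrostatic sorter outcome model

Actuated sorting success is a logistic surface over potential $V$
(V$_{\mathrm{RMS}}$), spacer flow $Q$ (nL/s), their interaction and
droplet volume:
$P = \mathrm{logit}^{-1}(\beta_0 + \beta_V V + \beta_Q Q + \beta_{VQ} VQ +
\beta_{vol}(v-1))$.
Two anchors pin the surface: $P = 0.5$ at (27.4 V$_{\mathrm{RMS}}$,
51.5 nL/s, 1 nL) and $P \approx 0.99$ in the efficient screening regime
(40 V$_{\mathrm{RMS}}$, 60 nL/s). Those two equations leave two degrees of
freedom, resolved by two design choices: the voltage main effect is fixed
at 0.15 per V$_{\mathrm{RMS}}$ (success monotone increasing in potential
everywhere in the characterized range) and the flow slope changes sign at
20 V$_{\mathrm{RMS}}$ — below it more flow hurts (drag defeats the field:
the E1 failure topology), above it more flow helps (enough drag to commit
to the narrow disfavored channel: the E2 topology). The volume coefficient
is $-3$/nL: smaller droplets sort more reliably, and success stays above
0.5 for volumes below ~1 nL in the polydisperse regimes
(36.34 V$_{\mathrm{RMS}}$/60 nL/s, 44.2 V$_{\mathrm{RMS}}$/80 nL/s). The
calibrated coefficients are data, not code — they ship in a versioned YAML
(`inst/extdata/routing_model_default.yaml`) and `calibrateRoutingModel()`
re-derives them from the anchors.

Unpulsed droplets take the wide main channel with the passive fidelity:
0.995 at 80 nL/s and 0.992 at 60 nL/s (linear in between, a plateau down
to 10 nL/s, and a linear collapse below 10 nL/s where large plugs raise
the main-channel resistance). On an actuated failure the mode is
classified by regime: E1 (escape into main) at low potential with high
flow, E2 (abandon/stall) at low flow, E3 (merge with the next arrival)
substituted when the gap to the next droplet is shorter than the pulse.

Known limitation: a single monotone bilinear logistic cannot reproduce
every reported observation — perfect sorting observed at
12.5 V$_{\mathrm{RMS}}$/50 nL/s and a successful autonomous calibration
run at 15 V$_{\mathrm{RMS}}$/30 nL/s both lie well below the
$P=0.5$ contour implied by the printed inflection anchor. The model
follows the anchors; closed-loop simulations therefore operate in the
screening regimes (~40 V$_{\mathrm{RMS}}$, 60–80 nL/s). Likewise only the
anchored points and the regime topology of the efficiency surface are
reproduced, not the full polynomial-fitted heatmap.

# Screening statistics

* **Efficiency GLM.** `fitBinomialGLM()` fits the logit-link binomial
  regression of per-cell successes on $V$, $Q$ and $V\!\times\!Q$ by
  IRLS (deviance tolerance $10^{-8}$). The response is per-cell binomial
  and the AIC uses the full binomial likelihood including the
  combinatorial term; per-attempt Bernoulli coding would give identical
  coefficients but a different AIC, so the convention is stated here
  once. Complete separation is detected and flagged rather than returned
  silently. `inflectionPoint()` solves the $P=0.5$ contour for one
  predictor with the other fixed. Droplet volume can enter as an optional
  covariate (`volumeCovariate`).
* **Confusion metrics.** Sensitivity $TP/(TP+FN)$ against condition
  positives, specificity $TN/(TN+FP)$ against negatives; marginals equal
  the droplet count.
* **Poisson encapsulation.** $\lambda$ from concentration × volume and
  the occupancy pmf, with expected occupied/single-spore counts.
* **Enzymatic activity.** The endpoint 4-MU assay formula
  $1.9 \cdot V_F \cdot DF \cdot (FLU - FLU_{blank}) /
  (FLU_{std} \cdot t \cdot V_{sample})$ in U/mL; a negative
  blank-corrected fluorescence clamps to zero with a warning because an
  assay cannot show negative product release. Fold change is the ratio to
  a reference (wild-type) activity.
* **Population comparison.** The variance test is the median-centred
  Levene variant (Brown–Forsythe) — more robust than mean-centring for
  skewed fluorescence data; skewness is Pearson's second coefficient
  $3(\mathrm{mean}-\mathrm{median})/\mathrm{sd}$ (the mode-based first
  coefficient is ill-defined on continuous data).
* **Exact binomial bound.** One-sided Clopper–Pearson lower confidence
  bound, used for statements like "main-channel probability greater than
  98.9% at 99.9% confidence".

# Numerical choices and degenerate inputs

* One integer seed controls each generator; vectorised draws follow a
  fixed documented order, and routing consumes one uniform per droplet
  indexed by position so matched runs (e.g. a pulsed session and its
  passive control) reuse identical draws for unpulsed droplets.
* Gate intervals are closed at both ends; "above the noise level" is
  strict. Quantiles are type 7.
* Frame streams are processed in ~200 s chunks whose boundaries are
  snapped to the global frame grid and placed mid-way through cold gaps,
  so chunking can never split a transit.
* Event–truth matching tolerates one part in $10^6$ of timing rounding;
  empty trains, empty event tables and header-only frame files are all
  legal inputs; malformed CSV rows are reported with their line number.
* Zero-variance groups in the variance test return a zero statistic
  (identical groups) or an infinite one with p = 0.
* Problem sizes in the shipped tests: sessions of 30–2000 s for
  distributional checks, one full 1800 s session for the throughput
  check, 100-replicate parameter-recovery and signal-recovery suites, and
  a 2000-replicate type-I-error simulation; each was chosen as the
  smallest size at which the corresponding statistic is stable.

# What the acceptance script recomputes

`scripts/acceptance.R` regenerates the headline session quantity from
scratch with the installed package: five seeded 30-minute sessions at
7 droplets/s are simulated, rendered to spectrometer frames, processed
through the full detection chain, and the mean number of detected droplet
events is written as `t1` (with the mean generated droplet count as the
problem size). No stored constants are involved; deleting the simulator
output and rerunning with another seed reproduces the quantity to within
Poisson noise.
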