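---
title: "Models and methods behind mmsync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mmsync}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mmsync` validates the temporal integration of a projection-based motion
lab with neurophysiological recordings. This vignette explains the models
the package implements, the parameters that matter, what the built-in
simulator does and does not emulate, and the numerical choices made where
the design was genuinely open. Nothing here states an empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The timing model

Every acquisition device stamps samples on its own clock, modeled as an
affine map of true time,

$$ t_{\mathrm{local}} = \mathrm{offset} + (1 + \mathrm{drift}) \, t_{\mathrm{true}}, $$

with drift in parts per million (`clock_model()`). Hardware drift is
near-linear over a session, so a first-order model suffices;
piecewise or spline clock models are out of scope. Mappings between clocks
are fitted by least squares on marker events observed on both clocks
(`fit_clock_mapping()`), using centered closed-form regression for
stability on large time values. On exact affine data the fit recovers
offset and drift to numerical precision (residual RMS below a nanosecond);
with white timestamp jitter of standard deviation $\sigma$ the residual
RMS estimates $\sigma$.

The display chain adds structure on top of the clocks: a stimulation
command is executed at the script rate (300 Hz) but only becomes light at
the next frame boundary (60 Hz), plus a fixed projector latency (default
50 ms). A photodiode watching a blinking encoding dot on the screen sees
events with exactly this full delay, which is why all event-related
analyses lock to *decoded photodiode times* and never to software command
times (`compensate_display_delay()`); the package treats this as a policy
with an audit trail rather than a computation.

### The two-script fault

The failure mode the jitter diagnostic targets: stimulus drawing and
photodiode blink issued by two separate scripts chained by an event. Since
script execution (300 Hz) outpaces frame generation (60 Hz), the blink can
land one or more frames after the stimulus, producing a variable
stimulus-to-blink delay with an observed envelope of roughly 12–56 ms. The
simulator models the realized envelope directly — blink time = stimulus
display time + $U(12, 56)$ ms — because the envelope is what was observed
and it already reflects the frame mechanism behind it; re-quantizing a
draw from the observed envelope onto the frame grid would widen it beyond
what was measured. The distribution within the envelope is not reported
anywhere, so uniform is an assumption.

`delay_report()` computes per-event delays (decoded blink − command) on a
common clock, optionally net of a known constant display latency, and
flags a session as jittered when the delay *range* exceeds half a frame
period (8.33 ms at 60 Hz): a delay constant up to frame quantization is
synchronous for a frame-locked display; anything larger indicates the
fault.

## The photodiode byte codec

Events are transmitted as one byte per event. The on-screen framing — 1
start bit (high), 8 data bits LSB-first, 1 stop bit (low), two display
frames per bit — is a package convention: start/stop framing makes the
decoder self-synchronizing, and two frames per bit tolerate a dropped
frame. All framing parameters are configurable (`codec_config()`) so an
alternative encoding needs no code change.

Digitization is a Schmitt trigger with hysteresis (defaults 0.6 V / 0.4 V
on a 0–1 V trace): the output switches high only above the upper
threshold and low only below the lower one, so noise inside the band never
retriggers. Decoding samples each bit at its temporal midpoint (robust to
±1 sample edge jitter) and validates the stop bit; the event timestamp is
the start-bit rising edge — the instant a hardware trigger would latch,
which carries the projection delay that the architecture exploits. The
round trip is exact for all 256 codes at the default configuration and at
1–3 frames per bit, and survives Gaussian sensor noise of 0.1 V
(6 standard deviations below the hysteresis span per sample).

## Movement-onset detection from the center of pressure

The detector implements the kinetic rule: zero-phase second-order
Butterworth low-pass at 5 Hz on the anteroposterior (AP) and mediolateral
(ML) COP positions, per-sample first differences combined as
$c_i = \sqrt{\Delta AP_i^2 + \Delta ML_i^2}$, the first crossing of the
0.3 threshold located, and the local minimum of $c$ nearest to that
crossing with height at most 0.05 designated the onset.

Two conventions the detection rule needs but does not itself determine
are fixed here and exposed in
`cop_onset_config()`:

- **The unit of the thresholds.** "Arbitrary unit" is interpreted as mm of
  COP displacement per sample at 1000 Hz (the first difference of a
  mm-scaled trace). The statistic scales with the input, so input units
  and thresholds must be configured together; results on other exports may
  need re-calibration.
- **The search for the minimum** runs on both sides of the crossing within
  a 2 s radius; an exactly equidistant tie goes to the earlier minimum,
  because the onset physically precedes the excursion. A plateau of equal
  values counts once, at its first sample.

Per-trial quality control (`qc_trials()`) flags trials whose combined
derivative exceeds 0.05 anywhere in the pre-onset baseline, or with no
detectable onset. Flags are advisory: exclusion requires an explicit
list, mirroring the visual-inspection step of the original workflow.

## Event-related pipelines

**VEP.** Band-pass 0.01–40 Hz plus a 50 Hz notch, common-average
reference (skipped with a warning on single-channel input), epochs from
−500 to +400 ms around each decoded stimulus, per-epoch linear detrend,
baseline correction over −500 to −100 ms, and the mean across trials with
a 95% normal-approximation confidence band (adequate at 50–120 trials).
N75 is the most negative point in 50–90 ms, P100 the most positive in
70–150 ms; the windows follow standard pattern-reversal practice (the detection
rule itself does not prescribe them) and are configurable because atypical
latencies may clip (a clipped search is flagged, not silently truncated).
An `artifact_correction` hook (default: identity) marks where
ocular-artifact ICA would sit in a production pipeline; ICA itself is an
off-the-shelf step irrelevant to synchronization validation.

**EMG.** DC removal over the full recording, rectification, a centered
moving average over 100 samples (centering preserves burst-onset timing
symmetry, where a causal filter would delay it), epochs from −5 to
+15 s around the *kinetic* onsets — never the EMG's own burst times — and
the ensemble mean with confidence band. The rectified trace is averaged
without detrending: it is strictly non-negative and its baseline level is
informative.

**fNIRS.** Intensities at 760 and 850 nm are converted to optical density
$OD(t) = -\log_{10} I(t)/\bar I$ and then to concentration changes of
oxygenated and deoxygenated hemoglobin by solving the 2×2 extinction
system with pathlength = source-detector distance × differential
pathlength factor (modified Beer–Lambert law). The extinction
coefficients are standard compiled tabulations of Gratzer's spectra
(1486.59 / 3843.71 cm⁻¹ M⁻¹ at 760 nm and 2526.39 / 1798.64 at 850 nm
for HbO₂/HbR) and the DPF of 6.0 is the conventional adult value; both
are hardware-dependent quantities exposed as configuration
(`fnirs_geometry()`). A 0.02–0.2 Hz band-pass removes drift and
cardiorespiratory frequencies; systemic physiology is then reduced by
ordinary least-squares regression of each long channel on its nearest
short channel (the ~1 cm channels sample mainly scalp), keeping the
residual. Epochs run −5 to +15 s around the kinetic onsets with baseline
−5 to −0.1 s. Shape metrics: initial dip = minimum in (0, 3) s, peak =
maximum in (3, 12) s, return time = first time after the peak with
absolute response below 10% of the peak.

## The simulator

`simulate_session()` composes task schedules, the display chain, the
codec, and per-modality signal generators into a bundle with full ground
truth (true display times, blink times, movement onsets, clock
parameters). Identical configuration and seed give bit-identical bundles.
The default conditions are the study's: 120 checkerboard reversals at
0.5 Hz over four minutes between 35 s rests; 50 start-to-go cycles of
15 s standing, a uniform 5–10 s wait, and a self-initiated step; EEG at
500 Hz, kinetics and EMG at 1000 Hz, fNIRS at 10 Hz; a minimal montage of
one occipital EEG channel, AP/ML COP, one EMG channel, and two long plus
one short fNIRS channel. The full 64-electrode and 43-channel montages
are hardware description, not algorithmic content.

Choices worth knowing about:

- **VEP template.** Gaussian components with the measured peak values
  (N75: 65 ms, −5.39 µV; P100: 90 ms, 9.15 µV) and widths of 10/12 ms
  *full width at half maximum*, which keeps the two lobes fully separate.
  The template specifies the response *as the analysis pipeline measures
  it*: reported peak values in this field are always post-filter, so the
  injected bumps are pre-compensated for the analysis band-pass and notch
  (a small fixed-point calibration) and the noise-free pipeline recovers
  the nominal values exactly. Without compensation the 40 Hz edge would
  attenuate bumps this narrow by roughly a fifth and the simulator would
  systematically undershoot the values it is supposed to emulate.
- **EEG background.** 1/f-shaped (amplitude ∝ 1/f above 0.1 Hz) noise at
  30 µV RMS, i.e. a single-trial peak signal-to-noise ratio of about 0.3
  against the P100 — single trials are dominated by slow drift the
  detrending removes, and averaging across the 120 trials is what makes
  the peaks measurable. After averaging, the residual background leaves
  roughly ±0.7 µV of run-to-run variation on the grand-average P100
  amplitude; this is genuine measurement noise of the design, not a bug.
- **EEG acquisition delay.** The constant ~10 ms delay of the EEG chain is
  modeled as common to the EEG samples and to the trigger path into the
  same recording chain, so it cancels in event-locked analysis — which is
  precisely why a *constant* delay is benign while a variable one is
  fatal. A diagnostic comparing the EEG-side markers to the control-side
  markers exposes the constant.
- **COP generator.** Quiet-stance sway is band-limited below 1 Hz at 2 mm
  RMS. Each step follows the gait-initiation sequence: an anticipatory
  postural adjustment (24 mm backward half-cosine over 250 ms), a brief
  motionless pause (80 ms, during which the active sway process also
  stops), and the step excursion (150 mm sigmoidal rise over 500 ms). The
  true onset is defined as the center of the pause — the moment swaying
  has ceased and stepping is about to commence, which is exactly the
  feature the local-minimum rule designates. Because the pause is wider
  than the 5 Hz smoothing kernel, the detected minimum stays pinned to it
  even if the step amplitude is doubled; with the defaults the detector
  recovers planted onsets to within a few milliseconds.
- **EMG bursts** begin 120 ms before the kinetic onset. Muscle
  activation is only constrained to precede the onset; 120 ms is a
  typical tibialis-anterior lead at gait initiation, is configurable
  (`emg_lead`), and is recorded in the session metadata.
- **Hemodynamic response.** Composite of gamma-density lobes plus a
  Gaussian initial dip, time-warped so the numerical maximum falls exactly
  at `peak_time` (default 7 s) with the configured amplitude (default
  0.6 µM); the initial dip sits near 1.4 s and the response is within 10%
  of baseline before 15 s. Deoxygenated hemoglobin is generated at −1/3
  the amplitude, lagged 1 s — conventional values.
  Systemic oscillations (0.1, 0.25, 1 Hz) enter the short channel fully
  and the long channels with weight 0.7; intensities are produced by the
  same modified Beer–Lambert forward model the analysis inverts, so
  forward/inverse consistency is exact (to 10⁻⁶ µM) on noise-free data.

What the simulator does **not** emulate: photorealistic scenario
rendering, treadmill-belt dynamics, 3D kinematics, multi-subject
variability, fNIRS time multiplexing and its modulation frequency, ocular
artifacts, and electrode/optode placement effects. Passing tests
demonstrate that the *pipelines implement their definitions correctly and
recover what the generators plant* under realistic rates, delays, and
noise — not that they are robust to every artifact of real recordings.
Threshold conventions (the COP unit question above all) may need
re-calibration on real exports.

## Numerical choices

- **Zero-phase filtering** is forward-backward application of
  `signal::butter` designs with odd (point-symmetric) end padding and
  steady-state initial conditions; padding length is three pole time
  constants, so start-up transients die inside the padding even at the
  0.01 Hz high-pass edge, whose poles sit within 10⁻⁴ of the unit circle.
  Band-passes are high-pass/low-pass cascades, numerically safer than a
  single fourth-order section when the edges are five decades apart.
- **Epoching** is resampling-free nearest-timestamp windowing with a fixed
  sample count per trial; events whose window leaves the recording are
  kept and flagged, never dropped.
- **Spectral noise synthesis** pads FFT lengths to the next 2/3/5-smooth
  integer (R's FFT is quadratic on awkward prime lengths) and truncates.
- **Sessions and problem sizes.** The test suite exercises scaled-down
  sessions (20 reversals, 6 walking cycles) for most properties and the
  full-scale sessions (120 reversals, 50 cycles) in the end-to-end
  checks; the acceptance script always runs full scale. These sizes are
  the study's own conditions, not a statistical choice.

## Known limitations

- The affine clock model cannot follow thermally induced drift changes
  within a session; residual statistics expose, but do not correct, such
  misfit.
- The onset thresholds are tied to the mm-per-sample convention; streams
  in meters or centimeters must be rescaled first.
- `read_xdf_subset()` parses the XDF container's numeric and string-marker
  streams only, does not apply clock-offset chunks, and is tested against
  byte-level fixtures assembled independently in the test helpers; it is a
  convenience importer, not a reference implementation.
- The short-channel correction uses a single nearest short channel per
  long channel; montages with several short channels per region would
  benefit from multi-regressor or component approaches that are out of
  scope here.
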