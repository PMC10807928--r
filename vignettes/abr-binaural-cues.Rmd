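---
title: "Quantifying ABRs and binaural acoustic cues with abrcues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ABRs and binaural acoustic cues with abrcues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abrcues)
```

# Scope

`abrcues` implements the analysis chain used to characterize hearing in a
small rodent from evoked potentials and acoustic measurements:

1. **Monaural ABR quantification** — band-pass filtering, epoch averaging,
   and peak-to-trough quantification of waves I–IV of the auditory brainstem
   response (ABR), with manual annotation support and ear averaging.
2. **Audiogram estimation** — an automated presence decision per stimulus
   level and the descending-step midpoint threshold rule, assembled into an
   audiogram over 1–46 kHz.
3. **Binaural interaction** — the binaural interaction component
   (BIC = binaural − (left + right)) and its first negative deflection (DN1)
   quantified across interaural time differences (ITDs).
4. **HRTF cue extraction** — swept-sine deconvolution, gain and directional
   transfer function (DTF) spectra, interaural level difference (ILD)
   spectra, and cross-correlation ITDs over a horizontal speaker grid.
5. **A synthetic-data generator** for all of the above, so that every stage
   can be validated end-to-end without animal recordings.

The reference parameter tables (`voleWaveParams()`, `voleBicParams()`,
`voleThresholds()`, `voleMorphometry()`) hold published group statistics for
prairie voles in the form mean ± standard error (range, N); they seed the
generator and the validation studies.

# The synthetic generator

## Wave templates

An epoch is modelled as

$$ x(t) = \sum_{w=1}^{4} a_w \, s(L)\, e^{-(t-\ell_w)^2 / 2\sigma_w^2}
          + \varepsilon(t), \qquad \varepsilon(t) \sim N(0, \sigma_n^2), $$

with per-wave amplitudes $a_w$ (µV), latencies $\ell_w$ (ms), template
widths $\sigma_w$, a level-dependent scale $s(L)$, and white epoch noise.
Epochs are 12 ms at 97 656.25 Hz, averaged over 500–1000 repetitions in the
emulated acquisition.

Three generator choices deserve explanation:

* **Template width** defaults to $\sigma_w = 0.15$ ms. The width is not a
  measured quantity; it is constrained from both sides. Too wide
  (≳ 0.25 ms) and adjacent waves at the group-mean latencies merge: the
  trough between waves rises and the measured peak-to-trough amplitude of a
  4.9 µV wave drops by more than 1 µV, so the generator would not mean what
  its parameters say. Too narrow (≲ 0.1 ms) and the template's energy moves
  above the 3 kHz analysis band. At 0.15 ms both effects are at the
  percent level.
* **Amplitudes follow the measurement convention.** Wave amplitudes in the
  group tables are peak-to-trough voltages of the band-passed (50–3000 Hz)
  average — that is how the analysis measures them. The generator therefore
  pre-compensates each wave template for the passband attenuation of an
  isolated wave of its width, so that the amplitude *parameter* equals the
  amplitude the pipeline *measures* (to within the small residual
  superposition of neighbouring waves). The injected DN1 deflection is
  compensated the same way.
* **Epoch noise** defaults to $\sigma_n = 3$ µV. No noise spectrum is
  specified for the emulated recordings; white noise band-limited by the
  downstream filter is the simplest defensible model. The level is set so
  that the averaged residual at 500 epochs (≈ 0.13 µV) sits well below the
  smallest group-mean wave amplitude (1.8 µV) while single epochs remain
  noise-dominated in the filter band.

## Between-animal variation

Group tables give mean ± SE with N, so the between-animal SD is
$\sqrt{N}\,\mathrm{SE}$. `simulateAnimals()` draws per-animal amplitudes
independently from $N(\mu, \sqrt{N}\,\mathrm{SE})$ (truncated at zero).
Latencies use the same per-wave marginals but share a single animal-level
standard normal factor: an animal slow on one wave is slow on all.
Physiologically, within-animal latency correlation across waves is the norm
(conduction velocity, temperature, head size act on the whole series), and
statistically, independent draws at these spreads would place wave III
within 0.3 ms of wave II in a nontrivial fraction of animals, destroying
the peak-to-trough measurement in a way real recordings do not.

For the binaural tables, each animal receives one latency offset (drawn with
the zero-ITD SD) applied across the whole DN1-vs-ITD curve, and one
amplitude scale factor (drawn with the zero-ITD coefficient of variation,
truncated at 0.1). Every simulated animal therefore keeps the canonical
curve shape — DN1 latency minimal near zero ITD — while the across-animal
spread at 0 ms matches the group table.

## Level growth and true threshold

`linearGrowth()` scales amplitudes linearly in dB between the true
threshold and 90 dB SPL, saturating at 1 above 90 and exactly 0 at or below
threshold. Only the stepping procedure is prescribed by the emulated
protocol; linear-in-dB growth is the simplest model with a hard threshold,
and the threshold estimator only relies on presence/absence, not the growth
shape.

## Acoustic scenes

`generateHrtfScene()` builds two-ear recordings of a logarithmic sweep
(250 Hz – 20 kHz, 131 072 samples ≈ 3 s at 44.1 kHz, −15 dBFS) through a
rigid-head model:

* **Interaural delay** follows the sine-of-azimuth law with maximum
  $(\text{pinna width} + \text{inter-pinna distance})/c$, split evenly
  across the two ears (right ear leads at positive azimuths). The simple
  quotient is used; the wrap-around (Woodworth) term for sources beyond the
  head shadow is deliberately omitted as the head is acoustically small over
  most of the measured band.
* **Head shadow** applies a frequency-dependent level difference
  $\mathrm{ILD}(f, \theta) = \mathrm{ILD}_{\max} \sin\theta \cdot
  f^2/(f^2 + f_c^2)$, i.e. negligible at low frequencies and approaching
  `maxIldDb` (default 18 dB, within the 15–20 dB range reported for
  small rodents at lateral positions) above the corner frequency (default
  4 kHz).
* Delays and gains are applied in the frequency domain, so
  fractional-sample delays are exact; a no-head calibration recording is
  produced with the common propagation delay and unit gain.

What the scene model does **not** emulate: pinna-specific spectral notches,
reflections and reverberation, measurement noise, and speaker
non-flatness. Passing the pipeline on these scenes validates the signal
path (deconvolution, windowing, spectra, cross-correlation) and the cue
conventions — it does not validate performance against room acoustics.

# Analysis choices

## Filtering

The analysis filter is a second-order Butterworth band-pass, 50–3000 Hz,
applied forward–backward (`signal::filtfilt`). Zero-phase application
doubles the effective order — the amplitude response is the squared
single-pass magnitude — but leaves peak latencies unbiased, which matters
because latency is a primary outcome. A causal single-pass mode
(`zeroPhase = FALSE`) is available for emulating hardware filters.

## Peak quantification

`detectPeaks()` takes the largest local maximum per wave window (ties to
the earlier sample), then the trough as the minimum between that peak and
the next wave's peak — the end of the trace for wave IV. "Between this peak
and the next" rather than a global minimum is deliberate: a global minimum
would make all waves share one trough. Default windows are centred on the
group-mean latencies for the chosen sex, ±0.6 ms, clipped at midpoints
between adjacent centres so windows never overlap. A wave is reported
absent when its amplitude falls below `minProminence` (default: twice the
RMS of the final 2 ms of the trace, assumed post-response). All defaults
are arguments, not constants.

## DN1 measurement

The BIC convention is binaural minus monaural sum, making DN1 a *negative*
deflection; amplitudes are reported as magnitudes so either sign convention
downstream reads the same. The monaural traces are summed without
time-shifting by the ITD. The DN1 search window defaults to 3.5–8 ms,
bracketing wave IV and the observed DN1 latency range across ITDs; presence
requires the deflection magnitude to reach twice the RMS of the BIC trace
outside the window.

## Threshold estimation

`responsePresent()` scores a trace by the ratio of its peak-to-peak voltage
in the response window (1–8 ms) to a peak-to-peak noise estimate (the final
2 ms, or a supplied noise reference), with presence at score ≥ 2. The score
is a ratio and thus scale-invariant — which also means its false-positive
rate on pure-noise levels (roughly 10 % at criterion 2 with these window
lengths) cannot be reduced by recording more epochs; it is governed by the
criterion and window geometry. The descending midpoint rule is robust to
such isolated false positives below threshold (the first absence governs),
and `estimateThreshold()` warns when decisions are non-monotone.

Thresholds from multiple-of-10 levels always end in 5 (midpoint of the last
present and first absent level); series with responses at every level or at
none are censored (`below_min` / `above_max`) rather than extrapolated.
Raising the criterion can only move the first absence to a higher level, so
threshold estimates are monotone in the criterion — this is a tested
property.

## HRTF pipeline

* **Deconvolution** convolves the recording with the amplitude-compensated
  time-reversed sweep (the standard log-sweep inverse filter). The result
  is normalized by the in-band spectral magnitude of the sweep's
  self-deconvolution, not by its time-domain peak: a band-limited impulse
  has a peak smaller than its in-band gain, and peak normalization would
  bias all gain spectra by ≈ 0.5 dB.
* **Spectra** use a 512-point FFT on a window starting 1 ms before the
  impulse-response peak. Gains are animal minus calibration in dB;
  fractional-octave smoothing (default 1/48 octave) is a Gaussian kernel in
  log2 frequency with SD = fraction/2, applied in the power domain with
  target-normalized weights so flat spectra pass unchanged.
* **DTF** subtracts the across-position mean gain per frequency; the DTFs
  average to 0 dB at every frequency by construction, and this is asserted
  to 0.01 dB.
* **ILD** is right minus left in dB. **ITD** is the lag maximizing the
  cross-correlation of the left and right impulse responses with parabolic
  sub-sample interpolation, positive when the right ear leads. Whether the
  "shift relative to the autocorrelation" should subtract the (zero)
  autocorrelation peak lag or normalize by it is ambiguous; subtraction is
  implemented. Cue summaries are meaningful within the swept band
  (0.25–20 kHz) only.
* `predictMaxItd()` and `pathLengthForItd()` implement the morphometric
  prediction ITD$_{\max}$ = (pinna width + inter-pinna distance)/c and its
  inverse; `effectiveDiameter()` is the equal-area-circle diameter
  $\sqrt{\ell w}$ of an elliptical pinna, which reproduces the published
  effective-diameter group means from the published length/width means to
  0.1 mm.

# Validation studies and their sizes

The test suite validates each stage against independent oracles (closed-form
filter responses, exhaustive-scan peak search, exhaustive lag search, direct
arithmetic) and the generator's ground truth. The two cohort-level studies
run at the emulated study's own scale — 9 animals × 500 epochs per ear for
the wave-recovery study, 9 animals × 9 ITDs for the DN1 study — which keeps
the full suite under a minute of simulation while matching the group sizes
the reference tables report. `scripts/acceptance.R` reruns both studies
from scratch at the same sizes.

Recovered group means are compared at two group standard errors. Note that
with per-animal parameters drawn at the table spreads, the cohort mean
itself has an SE equal to the table's SE, so a fixed-seed run lands within
2 SE with ≈ 95 % probability by construction — occasional excursions at
unlucky seeds are expected behaviour of the prescribed design, not a
pipeline defect.

# Known limitations

* **Wave II/III amplitudes are superposition-biased.** The trough between
  waves II and III sits on the flanks of both templates; recovered wave II
  amplitude underestimates its parameter by ~10–20 % under the female group
  geometry. Waves I and IV, whose troughs are cleaner, recover within a few
  percent. This is a property of peak-to-trough quantification on
  overlapping deflections, not of the detector.
* The noise model is white; real evoked-potential noise has 1/f structure,
  line interference and artifacts, none of which are emulated, and no
  artifact rejection beyond averaging is implemented.
* The audiogram presence decision replaces two trained human observers with
  a calibrated objective score; agreement holds for the synthetic noise
  model and criterion but has no claim to observer equivalence on real
  recordings.
* The scene model is horizontal-plane only, with no pinna spectral cues;
  vertical-plane grids are representable but no vertical pipeline is
  provided.
* Mixed-effects group inference is intentionally out of scope; the tidy
  feature tables (`peakFeatureTable()`, CSV exporters) are the interface to
  external modelling tools.
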