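---
title: "Locating and classifying nasal and oral elephant rumbles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating and classifying nasal and oral elephant rumbles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rumblecam)
```

`rumblecam` models one question end to end: given a low-frequency
elephant rumble recorded in front of a microphone array, did it radiate
from the trunk tip (nasal) or from the mouth (oral)? This vignette is
the package's own account of the models it implements, the parameters
that matter, and what its synthetic benchmark does and does not show.

## The production model

A rumble is treated as a source–filter signal. The glottal source is a
train of exponentially decaying pulses whose instantaneous rate follows
a slowly varying fundamental; the vocal tract is a uniform tube closed
at the vocal folds and open at the radiating end, whose resonances
(formants) sit at

$$F_n = \frac{(2n - 1)\,c}{4L}, \qquad n = 1, 2, \dots$$

with $c = 350$ m/s (warm, humid air inside the tract) and $L$ the
acoustic tract length. The closed–open geometry is what makes the
emission modes acoustically distinct: a ~2–2.2 m trunk path puts
$F_1$/$F_2$ near 40/120 Hz, while a ~0.6–0.8 m mouth path puts them
near 120/370 Hz — roughly a threefold shift. Adjacent formants are
spaced $\Delta F = c/(2L)$ apart, so the spacing inverts to tract
length, $\mathrm{VTL} = c\,/\,(2\,\Delta F)$, which is how
`estimate_vtl()` turns two measured formants into an anatomical length.

Two speeds of sound coexist deliberately: the tube model uses 350 m/s,
while propagation from the animal to the array uses 343 m/s (~20 °C
outdoor air). They are separate fields of `tube_model()` and
`propagation_model()` and are never shared implicitly.

## The synthesizer and what it emulates

`sample_call_population()` draws per-call parameters from the reported
per-class statistics — nasal: F0 $\sim N(19.7, 2.7)$ Hz, duration
$\sim N(2.94, 1.6)$ s (truncated at 0.5 s), SPL at 8 m
$\sim N(51.9, 6.22)$ dB, VTL $\sim U(1.80, 2.24)$ m; oral: F0
$\sim N(26.9, 4.6)$ Hz, duration $\sim N(1.79, 1.1)$ s, SPL
$\sim N(74.45, 7.49)$ dB, VTL $\sim U(0.63, 0.79)$ m. These defaults
are the study conditions and are not tuning knobs.

Choices the source data do not constrain, made once and documented
here:

* **Within-call F0 modulation** (`f0_sd_within`, default 1 Hz as a
  low-pass-filtered Gaussian walk, 2 Hz cut-off): rumbles have slow,
  arched pitch contours; a ~1 Hz SD produces a few Hz of drift over a
  call, enough to be realistic without threatening the pitch tracker's
  octave stability.
* **Pulse shape**: exponential decay with time constant 15% of the mean
  period. Only F0 and the formants matter downstream; the pulse shape
  fixes the source spectrum's overall tilt.
* **Resonator bandwidths**: 10% of centre frequency with a 10 Hz floor.
  Wider bandwidths (e.g. 30%) make the cascade's F1 skirt fall faster
  than the F2 resonance rises, so the radiated spectrum has *no local
  maximum at F2* and neither LPC nor any other envelope method can
  recover it; 10% keeps a local maximum within a few percent of every
  tube formant across the whole VTL range while staying broad enough
  for LPC peak-picking.
* **Number of formants**: 4. A uniform tube radiates the full odd
  quarter-wave series, and the upper formants carry most of the spatial
  localization information (see below).
* **SPL calibration**: waveforms are carried in pascals with digital
  full scale = 20 Pa; `spl_at_array` is the RMS level as received at
  the nominal 8 m array distance, and the scene simulator scales by
  `ref_distance / |r_i|` per microphone under spherical spreading.

`simulate_scene()` renders each call into the 48 channels with
fractional propagation delays (31-tap Hann-windowed sinc), 1/r
amplitude loss and independent white Gaussian background noise at a
configurable dB SPL. Nasal and oral emission points default to 0.8 m
vertical separation on the image plane — the approximate trunk-tip to
mouth distance — with the trunk tip below the mouth.

What the generator does **not** emulate: trunk-as-waveguide directivity,
atmospheric absorption, wind and reverberation, amplitude-modulated or
biphonic calls, and any within-call formant movement. Passing the tests
below therefore shows the *chain* is correct and self-consistent, not
that field recordings will behave this well.

## Beamforming and the allocation rule

The array geometry is a 3-arm, 16-microphone-per-arm star with
logarithmic radial spacing, scaled to a 3.4 m maximum aperture (the
commercial array's exact layout is unpublished; everything that depends
only on span and channel count is layout-independent, and the geometry
is configurable via JSON). Focusing compensates the relative run-time
delays $\Delta_i = \pi_i - \min_i \pi_i$: channel $i$ is *advanced* by
$\Delta_i$ and the weighted mean taken, so a source at the focus adds
coherently and the output equals the source waveform delayed by the
common minimum run time. A two-microphone example: mics at 8.00 m and
8.17 m from the source receive the wavefront 0.5 ms apart
($\Delta_2 = 0.5$ ms); advancing channel 2 by 0.5 ms re-aligns the two
copies. Dividing by $\sum w_i$ keeps a focused source at its physical
amplitude, which is what makes the per-pixel effective SPL
(Eq. RMS → dB re 20 µPa) interpretable and lets a calibrated synthetic
call round-trip to within ~1 dB.

Two numerically equivalent map implementations exist: a per-pixel
time-domain delay-and-sum (`method = "direct"`) and a lag-domain form
(`method = "lag"`, the default) that computes banded channel
cross-correlations once per window and evaluates
$\mathrm{rms}^2 \propto \sum_{ij} w_i w_j R_{ij}(d_i - d_j)$ per pixel
with the same windowed-sinc interpolation along the lag axis. They are
cross-checked in the test suite; the lag form is ~50× faster and makes
desk-scale mapping practical.

**Why allocation needs a band and a small margin.** With a 3.4 m
aperture at 8 m, the diffraction-limited resolution at rumble
frequencies is far coarser than the 0.8 m trunk–mouth separation: the
inter-point SPL contrast scales with $(\omega\,\delta)^2$, where
$\delta \approx 0.2$ ms is the typical delay mismatch, so at 40 Hz it
is effectively zero and even at 300 Hz it is a few tenths of a dB.
Nevertheless the map's *argmax* still falls on the true source — the
signal's own pattern peaks there and the beamformed noise at
neighbouring pixels is almost perfectly correlated, so it barely
perturbs the ranking. `allocate_scene()` therefore (1) high-passes the
channels at 100 Hz before mapping, removing the fundamental region
(which carries energy but no contrast) while keeping nasal F2–F4 and
oral F1–F2; and (2) uses a 0.05 dB ambiguity margin between the best
values in the two 0.3 m candidate disks. The margin was set against the
diffuse-field null: noise-only scenes produce inter-disk margins below
~0.05 dB (and their argmax almost never lands in a disk), while true
single-source scenes in the localization band give 0.07–0.13 dB. A
1 dB margin — natural-looking at first sight — would declare
essentially every infrasonic call ambiguous. Plain `acoustic_map()`
defaults to the full band so that map values remain physical SPL;
`peak_call_spl()` reads the mid-call movie frame on that scale.

## Measurement choices

* **Pitch**: frame-wise normalised autocorrelation (internally at
  2 kHz), time step 0.01 s, window 0.4 s, voicing threshold 0.45,
  silence threshold 0.03 of the call's peak frame RMS, parabolic lag
  interpolation. Ceilings follow the class: 35 Hz nasal, 40 Hz oral,
  floor 10 Hz.
* **Duration**: span where the smoothed 20 ms RMS envelope stays within
  25 dB of its peak. The threshold is a convention and is stated here
  rather than hidden; with the 50 ms synthesis ramps it recovers spec
  durations to within ~0.05 s.
* **Formants**: the 0.5 s mid-call segment is resampled to 6 kHz and an
  LPC envelope fitted; F1/F2 are the two lowest *envelope local maxima*
  in the class search band (below 150 Hz nasal, 400 Hz oral). Details
  that matter at infrasonic formants: the model order defaults to 42
  (the formants occupy a narrow slice of the 3 kHz band; low orders
  cannot resolve four resonances packed below ~300 Hz next to a
  wideband noise floor), with automatic retries at +12/+24 when fewer
  than two peaks resolve. Envelope maxima are used instead of LPC root
  frequencies because root bandwidths of genuine low formants routinely
  exceed classical "formant-like" gates. The search floor is
  pitch-adaptive (1.2×F0 nasal, max(80 Hz, 2.2×F0) oral) so the
  source's own harmonic peaks are not mistaken for F1 — anatomically,
  a mouth tract cannot put F1 below ~87 Hz — and the upper edge allows
  15% overshoot because short oral tracts (0.63–0.66 m) place true F2
  at 404–417 Hz, just above the nominal band. Residual error is
  dominated by harmonic sampling: the envelope is only observed at
  multiples of F0, so a single formant can be biased by up to ~F0/2,
  while the *spacing* F2−F1 (and hence VTL) is much less affected —
  median VTL error on the default populations is 2–5% per class.

## Classification

Each call is resampled to 1 kHz so that the 0–500 Hz descriptor band is
the full Nyquist range — this is what makes "model order 8"
meaningful — then an order-8 LPC envelope (dB scale) is evaluated on
260 bins per 300 ms window (30 ms step), averaged over time, and
block-averaged 10:1 to 26 components. One shared configuration object
is used for both classes. 260 bins is a convenience for clean 10:1
subsampling; doubling or halving it changes held-out accuracy on the
default corpus by nothing.

Before training, each descriptor's mean dB is removed (envelope *shape*
only) and components are z-scored with training-set statistics. Without
level removal, unusually quiet oral calls — the class SPL distributions
overlap by about two standard deviations — sit at nasal-like absolute
levels and pull SVM and nearest-neighbour decisions off; LDA is
insensitive but the protocol evaluates all three classifiers. Level
itself remains available to users as the `peak_spl` feature.

Evaluation follows the stated protocol: stratified 1/3 training : 2/3
evaluation split (stratification keeps both classes in the small
training third), 10-fold cross-validated selection of the SVM cost
(10^-2 … 10^2) and the neighbourhood size (1, 3, 5, 7), accuracy on the
held-out set, and a swap replicate with training and evaluation sets
exchanged. On the default synthetic corpus (60 + 60 calls, 20 dB SNR)
all three classifiers sit at or near 100% in both directions — the
synthetic classes are cleaner than real rumbles, which is exactly why
this corpus is a chain test, not a claim about field performance.

## Numerical conventions and degenerate inputs

Seeded randomness everywhere (`withr::with_seed`); a population, a
scene or a full `run_experiment()` replays bit-identically from its
config, and every output file carries the config hash. All-zero SPL
windows return `-Inf` ("below floor") rather than erroring; silent
calls measure duration 0 with a warning; calls shorter than the
formant segment or a descriptor window fall back to the full call with
a warning; formant measurement failures are recorded per call, never
thrown. Fractional delays use 31-tap Hann-windowed sinc interpolators
in both the simulator (R) and the beamformer (C++) — independent
implementations, compared only through tests, with exact-integer-delay
scenes providing the brute-force oracle.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen
as the package's own benchmark sizes: localization scenes at 8–16 kHz
with 24 × 18 pixel maps over the 4 × 3 m plane (the 0.3 m allocation
radius spans several pixels), 40-call allocation experiments, 50 calls
per class for parameter recovery, and a 120-call corpus for
classification. Call synthesis itself stays at the native 48 kHz.

## Known limitations

* The star array's true arm layout is unpublished; sidelobe-dependent
  results are layout-dependent by construction.
* The allocation margin and localization band were calibrated on this
  simulator's diffuse-noise null; a different noise field (wind,
  reverberation) would need a re-calibrated margin.
* Synthetic rumbles are stationary in formants and lack directivity,
  so the near-perfect classification accuracy here is an upper bound.
* Formant measurement inherits the harmonic-sampling bias of any
  envelope method at F0 ≳ formant bandwidth; VTL, which depends on the
  spacing, is the robust quantity.
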