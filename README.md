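# rumblecam

African elephants produce their low-frequency rumbles (fundamental around
15–30 Hz) either through the trunk — nasally — or through the mouth, and
the two modes carry different social information. Telling them apart from
audio alone is hard: the informative differences are the vocal-tract
resonances (formants), which for a ~2 m trunk sit at a few tens of Hz.
`rumblecam` re-implements, on synthetic data, the complete computational
chain used to study this problem with an acoustic camera:

1. **Source localization** — delay-and-sum beamforming of a 48-channel,
   3.4 m star array positioned ~8 m from the animal. The reconstructed
   signal at a point `x` on the image plane is

   `f(x, t) = (1 / Σ wᵢ) Σᵢ wᵢ fᵢ(t + Δᵢ)`, with `Δᵢ = πᵢ − min(πᵢ)`
   and `πᵢ = |rᵢ| / v`,

   and each pixel is coloured by its effective sound pressure level
   `L_p = 20 log₁₀(RMS / 20 µPa)`. A call is allocated **nasal** when the
   map peak falls around the trunk tip and **oral** when it falls around
   the mouth.

2. **Call acoustics** — autocorrelation pitch tracking (time step 0.01 s,
   window 0.4 s, band 10–35 Hz nasal / 10–40 Hz oral), waveform duration,
   and mid-call LPC formant measurement (0.5 s segment resampled to
   6 kHz). A uniform tube closed at the glottis and open at the trunk tip
   or mouth predicts formants `F_n = (2n − 1) c / (4 L)` with
   `c = 350 m/s`, and the formant spacing inverts to vocal tract length:
   `VTL = c / (2 ΔF)`.

3. **Automatic classification** — order-8 LPC spectrograms (300 ms
   window, 30 ms step, 0–500 Hz), time-averaged and subsampled to a
   26-component descriptor; LDA, a linear SVM and a nearest-neighbour
   classifier evaluated with a stratified 1/3 train : 2/3 evaluation
   split, 10-fold cross-validated tuning, and a train/eval swap
   replicate.

Because the original recordings are not publicly deposited, the package
ships a first-class synthetic-data module: a source–filter synthesizer
(glottal pulse train through a cascade of tube-model resonators,
calibrated in dB SPL at the array distance) whose population defaults
reproduce the published per-class statistics (nasal: F0 19.7 ± 2.7 Hz,
duration 2.94 ± 1.6 s, SPL 51.9 ± 6.22 dB, VTL 1.80–2.24 m; oral: F0
26.9 ± 4.6 Hz, duration 1.79 ± 1.1 s, SPL 74.45 ± 7.49 dB, VTL
0.63–0.79 m), and a scene simulator that renders calls from distinct
trunk-tip and mouth positions into the 48 microphone channels.

The package is aimed at bioacousticians who want a tested, scriptable
version of this pipeline — to benchmark localization/classification
ideas, to generate labelled infrasonic corpora, or to re-analyse their
own single-channel rumble recordings with the measurement half only.

## Worked example

```r
library(rumblecam)

# a labelled synthetic population with the published per-class statistics
pop   <- sample_call_population(n_nasal = 5, n_oral = 5, seed = 1)
calls <- synthesize_calls(pop)

# measure one call
featurize(calls$call[[1]], emission_hint = "nasal")
#> # A tibble: 1 x 11
#>   duration f0_min f0_max f0_range f0_mean f0_sd    f1    f2 vtl_est peak_spl failure
#>      <dbl>  <dbl>  <dbl>    <dbl>   <dbl> <dbl> <dbl> <dbl>   <dbl>    <dbl> <chr>
#> 1     1.57   17.1   19.7     2.68    18.1 0.986    37  114.    2.26     62.8 <NA>
```

The call was generated with VTL 2.01 m, mean F0 18.0 Hz, 61.3 dB SPL and
duration 1.63 s: the pitch track, duration, formant spacing (`vtl_est`)
and peak level all come back close to the ground truth. Localizing the
same call through the array:

```r
sc  <- scene_spec(place_calls(calls[1, ]), sample_rate = 16000)
sim <- simulate_scene(sc, seed = 1)
allocate_scene(sim, sc)
#> # A tibble: 1 x 9
#>   call_id   truth label peak_x peak_y peak_db peak_distance_nasal peak_distance_oral margin_db
#>   <chr>     <chr> <chr>  <dbl>  <dbl>   <dbl>               <dbl>              <dbl>     <dbl>
#> 1 nasal_001 nasal nasal 0.0317 -0.415    44.2              0.0351              0.816    0.0654
```

The map peak lands 3.5 cm from the trunk-tip reference point and the
call is allocated nasal. `autoplot()` on an `acoustic_map`, a `pitch_track`
or an evaluation object gives the corresponding ggplot2 displays, and
`run_experiment(run_config(...))` executes the full
synthesis → localization → features → classification chain into a run
directory with CSV/JSON outputs and a markdown summary.

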