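test_that("zero-jitter glottal source is exactly periodic", {
  src <- glottal_source(20, 0, 2.0, 48000, seed = 1)
  expect_length(src, 96000)
  onsets <- which(diff(c(0, src)) > 0.999)
  expect_equal(unique(diff(onsets)), 2400)   # 0.05 s at 48 kHz
})

test_that("glottal source is deterministic and matches its target F0", {
  a <- glottal_source(19.7, 2.7, 2.94, 48000, seed = 11)
  b <- glottal_source(19.7, 2.7, 2.94, 48000, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, glottal_source(19.7, 2.7, 2.94, 48000, seed = 12)))
  # autocorrelation oracle for the mean rate
  src <- glottal_source(26.9, 1.0, 1.79, 48000, seed = 5)
  ac <- acf(src, lag.max = 48000 / 15, plot = FALSE)$acf[-1]
  lag_min <- floor(48000 / 40)
  f0_hat <- 48000 / (lag_min - 1 + which.max(ac[lag_min:length(ac)]))
  expect_lt(abs(f0_hat - 26.9) / 26.9, 0.05)
  expect_error(glottal_source(20, 0, -1, 48000), "duration")
})

test_that("tube filter resonates at the closed-open formants", {
  withr::with_seed(2, wn <- rnorm(48000 * 4))
  y <- vocal_tract_filter(wn, 1.0, c = 350, n_formants = 2, sample_rate = 48000)
  sp <- stats::spec.pgram(stats::ts(y, frequency = 48000), spans = c(51, 51),
                          plot = FALSE, taper = 0)
  in1 <- sp$freq > 40 & sp$freq < 140
  in2 <- sp$freq > 180 & sp$freq < 340
  expect_lt(abs(sp$freq[in1][which.max(sp$spec[in1])] - 87.5) / 87.5, 0.05)
  expect_lt(abs(sp$freq[in2][which.max(sp$spec[in2])] - 262.5) / 262.5, 0.05)
})

test_that("formants above Nyquist are refused by name", {
  expect_error(vocal_tract_filter(rnorm(100), 0.3, c = 350, n_formants = 2,
                                  sample_rate = 1000),
               "formant 2")
  expect_error(vocal_tract_filter(rnorm(100), -1), "vtl")
})

test_that("synthesized calls carry their spec formants and calibration", {
  nasal <- test_call(vtl = 2.0, f0 = 20, spl = 52, seed = 9)
  fm <- measure_formants(nasal, "nasal")
  # F1 sits between the 2nd and 3rd source harmonics at F0 = 20 Hz, so its
  # envelope estimate carries a harmonic-sampling bias of up to ~F0/2;
  # the formant spacing (what VTL uses) is much less affected
  expect_lt(abs(fm$f1 - 43.75) / 43.75, 0.16)
  expect_lt(abs(fm$f2 - 131.25) / 131.25, 0.10)
  expect_lt(abs(estimate_vtl(fm$f1, fm$f2) - 2.0) / 2.0, 0.10)

  oral <- test_call(vtl = 0.7, f0 = 27, spl = 74, seed = 9)
  fo <- measure_formants(oral, "oral")
  expect_lt(abs(estimate_vtl(fo$f1, fo$f2) - 0.7) / 0.7, 0.10)

  # length contract and determinism
  expect_length(nasal$waveform, round(2.5 * 48000))
  again <- test_call(vtl = 2.0, f0 = 20, spl = 52, seed = 9)
  expect_identical(nasal$waveform, again$waveform)

  # RMS calibration at the array distance
  core <- nasal$waveform[seq(round(0.1 * 48000), length(nasal$waveform) - round(0.1 * 48000))]
  expect_lt(abs(effective_spl(core) - 52), 0.2)
})

test_that("population draws follow the per-class distributions", {
  pop <- sample_call_population(1000, 1000, seed = 33)
  nasal <- pop[pop$emission == "nasal", ]
  oral <- pop[pop$emission == "oral", ]
  expect_lt(abs(mean(nasal$f0_mean) - 19.7), 0.3)
  expect_lt(abs(mean(oral$f0_mean) - 26.9), 0.5)
  expect_true(all(nasal$vtl >= 1.80 & nasal$vtl <= 2.24))
  expect_true(all(oral$vtl >= 0.63 & oral$vtl <= 0.79))
  expect_true(all(pop$duration >= 0.5))
  expect_lt(abs(mean(nasal$spl_at_array) - 51.9), 0.7)
  expect_lt(abs(mean(oral$spl_at_array) - 74.45), 0.8)
  # determinism and the empty case
  expect_identical(pop, sample_call_population(1000, 1000, seed = 33))
  expect_equal(nrow(sample_call_population(0, 0, seed = 1)), 0)
})

test_that("scene simulation is symmetric, deterministic and Gaussian in noise", {
  # two mics equidistant from the source, noise off -> identical channels
  g <- array_geometry(rbind(c(-1, 0, 0), c(1, 0, 0)))
  call_row <- dplyr::mutate(sample_call_population(1, 0, seed = 2),
                            call = list(test_call(2.0, 20, duration = 1,
                                                  seed = 3, sample_rate = 8000)))
  call_row <- place_calls(call_row, nasal_position = c(0, 0, 8))
  sc <- scene_spec(call_row, array = g, plane = image_plane(nx = 2, ny = 2),
                   sample_rate = 8000, noise_spl = -Inf)
  sim <- simulate_scene(sc, seed = 1)
  expect_equal(sim$rec$samples[, 1], sim$rec$samples[, 2], tolerance = 1e-12)
  expect_identical(sim$rec$samples, simulate_scene(sc, seed = 1)$rec$samples)

  # noise-only scene: zero-mean Gaussian at the configured level
  sc2 <- scene_spec(dplyr::mutate(call_row,
                                  call = list(test_call(2.0, 20, duration = 0.2,
                                                        spl = -300, seed = 3,
                                                        sample_rate = 8000))),
                    array = g, plane = image_plane(nx = 2, ny = 2),
                    sample_rate = 8000, noise_spl = 60)
  sim2 <- simulate_scene(sc2, seed = 4)
  x <- as.numeric(sim2$rec$samples)
  expect_lt(abs(mean(x)) / sd(x), 0.01)
  expect_lt(abs(sd(x) - rumblecam:::db_to_pa(60)) / rumblecam:::db_to_pa(60), 0.05)
  expect_gt(shapiro.test(sample(x, 3000))$p.value, 1e-4)
})

test_that("noise injection hits the requested SNR and is reproducible", {
  cl <- test_call(0.7, 27, duration = 1, seed = 5)
  s_rms <- sqrt(mean(cl$waveform^2))
  noisy <- add_noise_snr(cl, 20, seed = 8)
  n_rms <- sqrt(mean((noisy$waveform - cl$waveform)^2))
  expect_lt(abs(20 * log10(s_rms / n_rms) - 20), 0.2)
  expect_identical(noisy$waveform, add_noise_snr(cl, 20, seed = 8)$waveform)
})

test_that("WAV round trip preserves multichannel audio", {
  withr::with_seed(6, x <- matrix(rnorm(600, 0, 0.5), 200, 3))
  for (bits in c(32, 16)) {
    path <- withr::local_tempfile(fileext = ".wav")
    write_wav(x, path, 8000, bits = bits)
    back <- read_wav(path)
    expect_equal(back$sample_rate, 8000)
    tol <- if (bits == 32) 1e-6 else 1e-3
    expect_equal(back$samples, x, tolerance = tol)
  }
})
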