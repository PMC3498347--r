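# shared fixtures, built in code

test_call <- function(vtl, f0, duration = 2.5, spl = 60, seed = 42,
                      emission = if (vtl > 1.2) "nasal" else "oral",
                      f0_sd = 1, sample_rate = 48000) {
  synthesize_call(
    list(emission = emission, vtl = vtl, f0_mean = f0, f0_sd_within = f0_sd,
         duration = duration, spl_at_array = spl, seed = seed),
    sample_rate = sample_rate
  )
}

as_recording <- function(samples, sample_rate) {
  structure(list(samples = samples, sample_rate = sample_rate),
            class = "multichannel_recording")
}

# single-call scene at its labelled emission point
single_call_scene <- function(call_row, sample_rate = 8000, noise_spl = 40,
                              nx = 24, ny = 18) {
  scene_spec(place_calls(call_row),
             array = build_star_array(),
             plane = image_plane(nx = nx, ny = ny),
             sample_rate = sample_rate, noise_spl = noise_spl)
}

# brute-force integer-shift-and-average beamformer (independent oracle)
shift_average <- function(x, shifts, weights = rep(1, ncol(x))) {
  n <- nrow(x)
  out <- numeric(n)
  for (j in seq_len(ncol(x))) {
    sh <- shifts[j]
    shifted <- numeric(n)
    if (sh == 0) shifted <- x[, j]
    else if (sh > 0 && sh < n) shifted[1:(n - sh)] <- x[(sh + 1):n, j]
    out <- out + weights[j] * shifted
  }
  out / sum(weights)
}
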