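# Source-filter synthesis of rumble calls.
#
# A rumble is modelled as a glottal pulse train (exponentially decaying
# pulses at a slowly modulated fundamental) passed through a cascade of
# second-order resonators at the closed-open tube-model formants, with a
# raised-cosine onset/offset and RMS calibration to a target dB SPL at the
# nominal recording distance.

#' Glottal source: band-limited pulse train with slow F0 modulation
#'
#' The instantaneous fundamental follows a low-pass-filtered Gaussian walk
#' (cut-off 2 Hz) rescaled to `f0_sd_within`; pulses are exponentially
#' decaying clicks placed by integrating the instantaneous frequency.
#'
#' @param f0_mean Mean fundamental frequency in Hz (>= 5).
#' @param f0_sd_within SD of the slow within-call F0 modulation in Hz.
#' @param duration Call duration in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @param seed Integer seed; output is bit-identical for equal seeds.
#' @return Numeric waveform of length `round(duration * sample_rate)`
#'   (unit-free; calibrated downstream).
#' @export
glottal_source <- function(f0_mean, f0_sd_within, duration, sample_rate,
                           seed = 1) {
  if (duration <= 0) stop("duration must be positive")
  if (f0_mean < 5) stop("f0_mean must be >= 5 Hz")
  n <- round(duration * sample_rate)
  f0_track <- withr::with_seed(seed, {
    if (f0_sd_within > 0) {
      ctrl_rate <- 100
      n_ctrl <- max(ceiling(duration * ctrl_rate), 8) + 8
      walk <- rnorm(n_ctrl)
      bf <- signal::butter(2, 2 / (ctrl_rate / 2), type = "low")
      sm <- signal::filtfilt(bf, walk)
      s <- sd(sm)
      if (s > 0) sm <- sm / s * f0_sd_within else sm <- sm * 0
      approx(seq_along(sm) / ctrl_rate, sm, xout = (seq_len(n) - 1) / sample_rate,
             rule = 2)$y + f0_mean
    } else {
      rep(f0_mean, n)
    }
  })
  f0_track <- pmax(f0_track, 5)
  phase <- cumsum(f0_track) / sample_rate
  pulse_idx <- which(diff(floor(c(0, phase))) >= 1)
  # exponentially decaying pulse shape, time constant 15% of mean period;
  # pulses are sparse, so place the kernel at each pulse directly
  tau <- 0.15 / f0_mean
  kt <- seq(0, 5 * tau, by = 1 / sample_rate)
  kernel <- exp(-kt / tau)
  y <- numeric(n + length(kernel))
  for (i in pulse_idx) {
    y[i:(i + length(kernel) - 1)] <- y[i:(i + length(kernel) - 1)] + kernel
  }
  y[seq_len(n)]
}

#' Tube-model vocal-tract filter
#'
#' Cascade of second-order resonators centred at the formants of a uniform
#' tube closed at the glottis and open at the mouth or trunk tip:
#' F_k = (2k - 1) c / (4 L). Resonator bandwidths default to 0.1 x centre
#' frequency (10 Hz floor), chosen so the cascade keeps a local spectral
#' maximum at every formant (wider skirts from the lower resonators
#' otherwise swallow the upper peaks) and LPC peak-picking resolves
#' infrasonic formants.
#'
#' @param source Input waveform.
#' @param vtl Vocal tract length in meters (> 0).
#' @param c Speed of sound in the tract in m/s (default 350).
#' @param n_formants Number of resonators in the cascade.
#' @param sample_rate Sampling rate in Hz.
#' @param bw_frac Bandwidth as a fraction of centre frequency.
#' @param bw_floor Minimum bandwidth in Hz.
#' @return Filtered waveform, same length as `source`.
#' @export
vocal_tract_filter <- function(source, vtl, c = 350, n_formants = 4,
                               sample_rate = 48000, bw_frac = 0.1,
                               bw_floor = 10) {
  if (vtl <= 0) stop("vtl must be positive")
  k <- seq_len(n_formants)
  f <- (2 * k - 1) * c / (4 * vtl)
  bad <- which(f >= sample_rate / 2)
  if (length(bad)) {
    stop(sprintf("formant %d (%.1f Hz) is at or above Nyquist (%.1f Hz)",
                 bad[1], f[bad[1]], sample_rate / 2))
  }
  y <- source
  for (i in k) {
    bw <- max(bw_frac * f[i], bw_floor)
    r <- exp(-pi * bw / sample_rate)
    th <- 2 * pi * f[i] / sample_rate
    y <- stats::filter(y, c(2 * r * cos(th), -r^2), method = "recursive")
    # normalise to unit gain at the resonance centre
    h <- 1 / abs(1 - 2 * r * cos(th) * exp(-1i * th) + r^2 * exp(-2i * th))
    y <- as.numeric(y) / h
  }
  y
}

#' Synthesize one calibrated rumble call
#'
#' Composes [glottal_source()] and [vocal_tract_filter()], applies 50 ms
#' raised-cosine onset/offset ramps, and scales the waveform so its RMS
#' equals the target dB SPL as received at `ref_distance` (the array
#' distance; under spherical spreading the source is `ref_distance` times
#' stronger at 1 m).
#'
#' @param spec A call spec: list or one-row data frame with fields
#'   `emission` ("nasal"/"oral"), `vtl` (m), `f0_mean`, `f0_sd_within` (Hz),
#'   `duration` (s), `spl_at_array` (dB SPL), `seed`.
#' @param sample_rate Sampling rate in Hz (default 48000).
#' @param ref_distance Distance at which `spl_at_array` applies (default 8 m).
#' @param n_formants Resonators in the tract cascade.
#' @return A `rumble_call`: list with `waveform` (Pa at `ref_distance`),
#'   `sample_rate`, `ref_distance` and `spec` (ground truth).
#' @export
synthesize_call <- function(spec, sample_rate = 48000, ref_distance = 8,
                            n_formants = 4) {
  spec <- as.list(spec)
  src <- glottal_source(spec$f0_mean, spec$f0_sd_within, spec$duration,
                        sample_rate, seed = spec$seed)
  y <- vocal_tract_filter(src, spec$vtl, c = 350, n_formants = n_formants,
                          sample_rate = sample_rate)
  n <- length(y)
  ramp_n <- min(round(0.05 * sample_rate), floor(n / 2))
  env <- rep(1, n)
  if (ramp_n > 0) {
    up <- 0.5 * (1 - cos(pi * seq_len(ramp_n) / ramp_n))
    env[seq_len(ramp_n)] <- up
    env[n - ramp_n + seq_len(ramp_n)] <- rev(up)
  }
  y <- y * env
  core <- y[max(ramp_n, 1):(n - max(ramp_n - 1, 0))]
  rms <- sqrt(mean(core^2))
  if (rms > 0) y <- y * (db_to_pa(spec$spl_at_array) / rms)
  structure(
    list(waveform = y, sample_rate = sample_rate,
         ref_distance = ref_distance, spec = spec),
    class = "rumble_call"
  )
}

#' @export
print.rumble_call <- function(x, ...) {
  cat(sprintf("<rumble_call %s: %.2f s @ %d Hz, F0 %.1f Hz, VTL %.2f m, %.1f dB SPL @ %g m>\n",
              x$spec$emission %||% "?", length(x$waveform) / x$sample_rate,
              x$sample_rate, x$spec$f0_mean, x$spec$vtl,
              x$spec$spl_at_array, x$ref_distance))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# population parameters measured from the recorded rumbles:
# F0, duration and SPL-at-8-m are per-class Normal; VTL is uniform over the
# per-individual range of tract lengths estimated from formant spacing.
population_defaults <- list(
  nasal = list(f0 = c(19.7, 2.7), duration = c(2.94, 1.6),
               spl = c(51.9, 6.22), vtl = c(1.80, 2.24)),
  oral = list(f0 = c(26.9, 4.6), duration = c(1.79, 1.1),
              spl = c(74.45, 7.49), vtl = c(0.63, 0.79))
)

#' Draw a population of rumble call specs
#'
#' Per-class parameters default to the field measurements: nasal rumbles
#' F0 ~ N(19.7, 2.7) Hz, duration ~ N(2.94, 1.6) s, SPL ~ N(51.9, 6.22) dB
#' at 8 m, VTL ~ U(1.80, 2.24) m; oral rumbles F0 ~ N(26.9, 4.6) Hz,
#' duration ~ N(1.79, 1.1) s, SPL ~ N(74.45, 7.49) dB, VTL ~ U(0.63,
#' 0.79) m. Durations are redrawn until >= 0.5 s; F0 until >= 8 Hz.
#'
#' @param n_nasal,n_oral Number of calls per class.
#' @param seed Integer seed.
#' @param f0_sd_within Within-call slow F0 modulation SD in Hz.
#' @return Tibble with one row per call: `call_id`, `emission`, `f0_mean`,
#'   `f0_sd_within`, `duration`, `spl_at_array`, `vtl`, `seed`.
#' @export
sample_call_population <- function(n_nasal, n_oral, seed = 1,
                                   f0_sd_within = 1) {
  stopifnot(n_nasal >= 0, n_oral >= 0)
  draw_class <- function(n, p, emission) {
    if (n == 0) return(NULL)
    rtrunc <- function(n, mean, sd, lower) {
      x <- rnorm(n, mean, sd)
      while (any(bad <- x < lower)) x[bad] <- rnorm(sum(bad), mean, sd)
      x
    }
    tibble::tibble(
      emission = emission,
      f0_mean = rtrunc(n, p$f0[1], p$f0[2], 8),
      f0_sd_within = f0_sd_within,
      duration = rtrunc(n, p$duration[1], p$duration[2], 0.5),
      spl_at_array = rtrunc(n, p$spl[1], p$spl[2], 20),
      vtl = runif(n, p$vtl[1], p$vtl[2])
    )
  }
  withr::with_seed(seed, {
    specs <- dplyr::bind_rows(
      draw_class(n_nasal, population_defaults$nasal, "nasal"),
      draw_class(n_oral, population_defaults$oral, "oral")
    )
    if (is.null(specs) || nrow(specs) == 0) {
      return(tibble::tibble(
        call_id = character(), emission = character(), f0_mean = numeric(),
        f0_sd_within = numeric(), duration = numeric(),
        spl_at_array = numeric(), vtl = numeric(), seed = integer()
      ))
    }
    specs$seed <- sample.int(.Machine$integer.max - 1, nrow(specs))
    specs$call_id <- sprintf("%s_%03d", specs$emission,
                             stats::ave(seq_len(nrow(specs)), specs$emission,
                                        FUN = seq_along))
    dplyr::select(specs, "call_id", "emission", "f0_mean", "f0_sd_within",
                  "duration", "spl_at_array", "vtl", "seed")
  })
}

#' Synthesize every call in a population table
#'
#' @param specs Tibble from [sample_call_population()] (or compatible).
#' @param sample_rate,ref_distance,n_formants Passed to [synthesize_call()].
#' @return The input tibble with a `call` list-column of `rumble_call`s.
#' @export
synthesize_calls <- function(specs, sample_rate = 48000, ref_distance = 8,
                             n_formants = 4) {
  specs$call <- purrr::pmap(
    dplyr::select(specs, "emission", "f0_mean", "f0_sd_within", "duration",
                  "spl_at_array", "vtl", "seed"),
    function(...) synthesize_call(list(...), sample_rate = sample_rate,
                                  ref_distance = ref_distance,
                                  n_formants = n_formants)
  )
  specs
}

#' Add white Gaussian noise at a target signal-to-noise ratio
#'
#' @param call A `rumble_call`.
#' @param snr_db Target SNR in dB (signal RMS over noise RMS).
#' @param seed Integer seed.
#' @return A `rumble_call` with noise added to the waveform.
#' @export
add_noise_snr <- function(call, snr_db, seed = 1) {
  s_rms <- sqrt(mean(call$waveform^2))
  n_rms <- s_rms / 10^(snr_db / 20)
  call$waveform <- call$waveform +
    withr::with_seed(seed, rnorm(length(call$waveform), 0, n_rms))
  call
}
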