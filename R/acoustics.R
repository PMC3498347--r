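# Per-call acoustic measurement: pitch, duration, formants, vocal tract
# length from formant spacing.

#' Uniform-tube vocal tract model
#'
#' A tube closed at the glottis and open at the mouth or trunk tip. The
#' speed of sound defaults to 350 m/s (body-temperature humid air inside
#' the tract), distinct from the 343 m/s used for outdoor propagation.
#'
#' @param c Speed of sound in m/s.
#' @export
tube_model <- function(c = 350) {
  if (c <= 0) stop("speed of sound must be positive")
  structure(list(c = c, closed_open = TRUE), class = "tube_model")
}

#' Predicted formant frequencies of a closed-open tube
#'
#' F_k = (2k - 1) c / (4 L): odd quarter-wavelength resonances. For the
#' 2.5 m nasal tract this gives F1 = 35, F2 = 105 Hz; for the 0.75 m oral
#' tract F1 = 116.7, F2 = 350 Hz.
#'
#' @param vtl Vocal tract length L in meters (> 0).
#' @param k Formant index (vectorised).
#' @param model A [tube_model()].
#' @return Formant frequencies in Hz.
#' @export
predict_formants <- function(vtl, k = 1:2, model = tube_model()) {
  if (any(vtl <= 0)) stop("vtl must be positive")
  if (any(k < 1)) stop("formant index must be >= 1")
  (2 * k - 1) * model$c / (4 * vtl)
}

#' Vocal tract length from formant spacing
#'
#' VTL = c / (2 * (F2 - F1)): for a uniform closed-open tube adjacent
#' formants are spaced c / (2 L) apart, so the spacing inverts to the
#' acoustic tract length.
#'
#' @param f1,f2 First and second formant frequencies in Hz (f2 > f1 > 0).
#' @param model A [tube_model()].
#' @return Vocal tract length in meters.
#' @export
estimate_vtl <- function(f1, f2, model = tube_model()) {
  if (any(f1 <= 0) || any(f2 <= f1)) stop("need f2 > f1 > 0")
  model$c / (2 * (f2 - f1))
}

#' Autocorrelation pitch track
#'
#' Frame-wise normalised autocorrelation with candidates restricted to
#' [floor_hz, ceiling_hz]; frames whose autocorrelation peak falls below
#' `voicing_threshold`, or whose level falls below `silence_threshold`
#' times the call peak, are unvoiced. The defaults mirror standard
#' practice for infrasonic calls: time step 0.01 s, window 0.4 s, floor
#' 10 Hz, ceiling 35 Hz (nasal) or 40 Hz (oral).
#'
#' @param call A `rumble_call` (or list with `waveform`, `sample_rate`).
#' @param floor_hz,ceiling_hz Pitch search range in Hz.
#' @param time_step Frame step in seconds.
#' @param window Analysis window length in seconds (>= 2 periods at
#'   `floor_hz`).
#' @param voicing_threshold Minimum normalised autocorrelation (default
#'   0.45).
#' @param silence_threshold Minimum frame RMS relative to the call's peak
#'   frame RMS (default 0.03).
#' @return A `pitch_track`: tibble with `time`, `f0` (NA when unvoiced),
#'   `strength`, `voiced`; settings stored as attributes.
#' @export
extract_pitch <- function(call, floor_hz = 10, ceiling_hz = 35,
                          time_step = 0.01, window = 0.4,
                          voicing_threshold = 0.45,
                          silence_threshold = 0.03) {
  if (window < 2 / floor_hz) stop("window too short for two periods at the pitch floor")
  fs0 <- call$sample_rate
  dur <- length(call$waveform) / fs0
  if (dur < window) stop("call shorter than one analysis window")
  fsd <- 2000
  x <- resample_to(call$waveform, fs0, fsd)
  nw <- round(window * fsd)
  lag_min <- max(floor(fsd / ceiling_hz), 2)
  lag_max <- min(ceiling(fsd / floor_hz), nw - 1)
  centers <- seq(window / 2, dur - window / 2, by = time_step)
  frame_rms <- vapply(centers, function(tc) {
    i0 <- round((tc - window / 2) * fsd) + 1
    seg <- x[i0:min(i0 + nw - 1, length(x))]
    sqrt(mean((seg - mean(seg))^2))
  }, numeric(1))
  peak_rms <- max(frame_rms)
  res <- lapply(seq_along(centers), function(k) {
    if (peak_rms == 0 || frame_rms[k] < silence_threshold * peak_rms) {
      return(c(NA_real_, 0))
    }
    i0 <- round((centers[k] - window / 2) * fsd) + 1
    seg <- x[i0:min(i0 + nw - 1, length(x))]
    seg <- seg - mean(seg)
    nfft <- 2^ceiling(log2(2 * length(seg)))
    S <- fft(c(seg, numeric(nfft - length(seg))))
    r <- Re(fft(Mod(S)^2, inverse = TRUE)) / nfft
    if (r[1] <= 0) return(c(NA_real_, 0))
    r <- r / r[1]
    lags <- lag_min:lag_max
    pk <- which.max(r[lags + 1])
    lag <- lags[pk]
    strength <- r[lag + 1]
    # parabolic interpolation around the peak
    if (lag > lag_min && lag < lag_max) {
      y0 <- r[lag]; y1 <- r[lag + 1]; y2 <- r[lag + 2]
      den <- y0 - 2 * y1 + y2
      if (abs(den) > 1e-12) lag <- lag + 0.5 * (y0 - y2) / den
    }
    c(fsd / lag, strength)
  })
  res <- do.call(rbind, res)
  voiced <- !is.na(res[, 1]) & res[, 2] >= voicing_threshold
  out <- tibble::tibble(
    time = centers,
    f0 = ifelse(voiced, res[, 1], NA_real_),
    strength = res[, 2],
    voiced = voiced
  )
  attr(out, "settings") <- list(time_step = time_step, window = window,
                                floor_hz = floor_hz, ceiling_hz = ceiling_hz)
  class(out) <- c("pitch_track", class(out))
  out
}

#' Call duration from the smoothed energy envelope
#'
#' The duration is the span over which the smoothed short-term RMS
#' envelope exceeds its peak minus `threshold_db` (default 25 dB; stated
#' in the feature metadata).
#'
#' @param call A `rumble_call`.
#' @param threshold_db Drop below the envelope peak in dB.
#' @return Duration in seconds (0, with a warning, for silence).
#' @export
measure_duration <- function(call, threshold_db = 25) {
  x <- call$waveform
  if (length(x) == 0) stop("empty waveform")
  fs <- call$sample_rate
  hop <- max(round(0.005 * fs), 1)
  win <- max(round(0.02 * fs), 2)
  starts <- seq(1, max(length(x) - win + 1, 1), by = hop)
  env <- vapply(starts, function(i)
    sqrt(mean(x[i:min(i + win - 1, length(x))]^2)), numeric(1))
  env <- as.numeric(stats::filter(env, rep(1 / 5, 5), sides = 2))
  env[is.na(env)] <- 0
  pk <- max(env)
  if (pk == 0) {
    warning("silent input; duration 0")
    return(0)
  }
  above <- which(env > pk * 10^(-threshold_db / 20))
  (max(above) - min(above) + 1) * hop / fs
}

#' Measure formants 1 and 2 by mid-call LPC
#'
#' Takes the 0.5 s segment starting at the call midpoint (whole call, with
#' a warning, if shorter), resamples to 6000 Hz, fits an LPC model and
#' returns the two lowest local maxima of its spectral envelope below
#' 150 Hz (nasal hint) or 400 Hz (oral hint) — the peak-search bands
#' implied by the tube-model predictions for ~2.5 m and ~0.75 m tracts.
#'
#' Infrasonic formants sit in a narrow slice of the 3 kHz analysis band,
#' so the default order is high (42) and, when the envelope resolves
#' fewer than two peaks, the fit is retried at order + 12 and + 24 before
#' a measurement failure is recorded.
#'
#' @param call A `rumble_call`.
#' @param emission_hint "nasal" or "oral".
#' @param order Starting LPC order at 6 kHz (default 42).
#' @return One-row tibble with `f1`, `f2` (NA plus a `failure` message when
#'   fewer than two peaks are found; never an exception).
#' @export
measure_formants <- function(call, emission_hint = c("nasal", "oral"),
                             order = 42) {
  emission_hint <- match.arg(emission_hint)
  fmax <- if (emission_hint == "nasal") 150 else 400
  fs <- call$sample_rate
  x <- call$waveform
  need <- round(0.5 * fs)
  if (length(x) < need) {
    warning("call shorter than 0.5 s; using the full call")
    seg <- x
  } else {
    mid <- floor(length(x) / 2)
    seg <- x[(mid + 1):min(mid + need, length(x))]
  }
  fsd <- 6000
  seg <- resample_to(seg, fs, fsd)
  # pitch-adaptive search floor: keep the glottal fundamental's own spectral
  # peak (at ~F0) from being mistaken for F1
  ac <- Re(fft(Mod(fft(c(seg - mean(seg), numeric(length(seg)))))^2,
               inverse = TRUE))
  lags <- round(fsd / 45):round(fsd / 8)
  f0_est <- fsd / lags[which.max(ac[lags + 1])]
  # class-specific floors: the lowest anatomically plausible F1 is ~29 Hz
  # for a <= 3 m trunk tract and ~87 Hz for a <= 1 m mouth tract, and the
  # first source harmonics must stay below the search band
  fmin <- if (emission_hint == "nasal") {
    max(25, 1.2 * f0_est)
  } else {
    max(80, 2.2 * f0_est)
  }
  fr <- seq(5, fmax + 60, by = 0.5)
  floor_static <- if (emission_hint == "nasal") 25 else 80
  for (lo in unique(c(fmin, floor_static))) {
    for (ord in order + c(0, 12, 24)) {
      if (ord >= length(seg)) break
      lp <- lpc_coeffs(seg, ord)
      env <- lpc_envelope_db(lp, fr, fsd)
      loc <- which(diff(sign(diff(env))) == -2) + 1
      pk <- fr[loc]
      # the upper formant may straddle the band edge (field F2 values run
      # up to ~453 Hz against the 400 Hz oral search band): 15% overshoot
      pk <- pk[pk >= lo & pk <= 1.15 * fmax]
      if (length(pk) >= 2) {
        return(tibble::tibble(f1 = pk[1], f2 = pk[2], failure = NA_character_))
      }
    }
  }
  tibble::tibble(f1 = NA_real_, f2 = NA_real_,
                 failure = sprintf("fewer than 2 envelope peaks below %d Hz", fmax))
}

#' Peak SPL of a call waveform
#'
#' Maximum 50 ms RMS level in dB SPL; with calls calibrated at the array
#' distance this corresponds to the peak level as received at the array.
#'
#' @param call A `rumble_call`.
#' @return dB SPL.
#' @export
call_peak_spl <- function(call) {
  fs <- call$sample_rate
  win <- max(round(0.05 * fs), 2)
  x <- call$waveform
  starts <- seq(1, max(length(x) - win + 1, 1), by = max(round(win / 2), 1))
  env <- vapply(starts, function(i)
    sqrt(mean(x[i:min(i + win - 1, length(x))]^2)), numeric(1))
  if (max(env) == 0) return(BELOW_FLOOR_DB)
  pa_to_db(max(env))
}

#' Full acoustic feature set for one call
#'
#' Composes duration, pitch statistics, formants, VTL and peak SPL. The
#' pitch ceiling follows the emission hint (35 Hz nasal, 40 Hz oral).
#'
#' @param call A `rumble_call`.
#' @param emission_hint "nasal" or "oral".
#' @return One-row tibble: `duration`, `f0_min`, `f0_max`, `f0_range`,
#'   `f0_mean`, `f0_sd`, `f1`, `f2`, `vtl_est`, `peak_spl`, `failure`.
#' @export
featurize <- function(call, emission_hint = c("nasal", "oral")) {
  emission_hint <- match.arg(emission_hint)
  ceiling_hz <- if (emission_hint == "nasal") 35 else 40
  dur <- measure_duration(call)
  pt <- extract_pitch(call, floor_hz = 10, ceiling_hz = ceiling_hz)
  f0 <- pt$f0[pt$voiced]
  fm <- measure_formants(call, emission_hint)
  vtl <- if (!is.na(fm$f1) && !is.na(fm$f2) && fm$f2 > fm$f1) {
    estimate_vtl(fm$f1, fm$f2)
  } else NA_real_
  tibble::tibble(
    duration = dur,
    f0_min = if (length(f0)) min(f0) else NA_real_,
    f0_max = if (length(f0)) max(f0) else NA_real_,
    f0_range = if (length(f0)) max(f0) - min(f0) else NA_real_,
    f0_mean = if (length(f0)) mean(f0) else NA_real_,
    f0_sd = if (length(f0) > 1) sd(f0) else NA_real_,
    f1 = fm$f1, f2 = fm$f2, vtl_est = vtl,
    peak_spl = call_peak_spl(call),
    failure = fm$failure
  )
}

#' Measure features for every call in a population table
#'
#' @param calls Tibble with `call` list-column and `emission` column (used
#'   as the measurement hint).
#' @return The input columns `call_id`, `emission` joined with one feature
#'   row per call.
#' @export
measure_calls <- function(calls) {
  feats <- purrr::map2(calls$call, calls$emission,
                       function(cl, em) featurize(cl, em))
  dplyr::bind_cols(
    calls[, intersect(c("call_id", "emission"), names(calls))],
    dplyr::bind_rows(feats)
  )
}


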