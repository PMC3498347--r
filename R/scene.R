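# Scene simulation: render calibrated calls at source positions into the
# per-microphone channels of the array, with fractional propagation delays,
# spherical spreading and diffuse Gaussian background noise.

#' Scene description for multichannel simulation
#'
#' Nasal (trunk-tip) and oral (mouth) emission points default to two
#' positions on the image plane 0.8 m apart vertically — the approximate
#' trunk-tip-to-mouth separation that makes the two emission modes
#' distinguishable on the acoustic map (trunk tip below the mouth).
#'
#' @param calls Tibble with list-column `call` (`rumble_call`s) and columns
#'   `x`, `y`, `z` (source position, m) and `onset` (s). Helper
#'   [place_calls()] builds it from a synthesized population.
#' @param array An `array_geometry` (default [build_star_array()]).
#' @param plane An `image_plane`.
#' @param propagation A `propagation_model`.
#' @param noise_spl Diffuse background level per channel in dB SPL
#'   (default 40, quiet outdoor ambience).
#' @param sample_rate Scene sampling rate in Hz (default 48000).
#' @param nasal_position,oral_position Reference emission points (length 3).
#' @export
scene_spec <- function(calls,
                       array = build_star_array(),
                       plane = image_plane(),
                       propagation = propagation_model(),
                       noise_spl = 40,
                       sample_rate = 48000,
                       nasal_position = c(0, -0.4, plane$distance),
                       oral_position = c(0, 0.4, plane$distance)) {
  if (sqrt(sum((nasal_position - oral_position)^2)) < 1e-6) {
    stop("nasal and oral positions must be distinct")
  }
  structure(
    list(calls = calls, array = array, plane = plane,
         propagation = propagation, noise_spl = noise_spl,
         sample_rate = sample_rate,
         nasal_position = as.numeric(nasal_position),
         oral_position = as.numeric(oral_position)),
    class = "scene_spec"
  )
}

#' Place synthesized calls at their emission points
#'
#' @param calls Tibble with `call` list-column and an `emission` column.
#' @param nasal_position,oral_position Length-3 coordinates.
#' @param onsets Onset time for each call in seconds (default all 0,
#'   i.e. one call per scene or simultaneous calls).
#' @return The tibble with `x`, `y`, `z`, `onset` columns added.
#' @export
place_calls <- function(calls, nasal_position = c(0, -0.4, 8),
                        oral_position = c(0, 0.4, 8), onsets = 0) {
  pos <- t(vapply(calls$emission, function(e) {
    if (identical(e, "nasal")) nasal_position else oral_position
  }, numeric(3)))
  calls$x <- pos[, 1]
  calls$y <- pos[, 2]
  calls$z <- pos[, 3]
  calls$onset <- rep_len(onsets, nrow(calls))
  calls
}

# fractional delay of x by d >= 0 samples via Hann-windowed sinc (R-side
# renderer; the beamformer uses an independent compiled interpolator)
fractional_delay <- function(x, d, n_taps = 31) {
  d_int <- floor(d)
  frac <- d - d_int
  n <- length(x)
  out <- numeric(n)
  if (frac < 1e-12) {
    if (d_int < n) out[(d_int + 1):n] <- x[1:(n - d_int)]
    return(out)
  }
  half <- n_taps %/% 2
  ks <- (-half + 1):half
  u <- ks - frac
  kern <- ifelse(u == 0, 1, sin(pi * u) / (pi * u)) *
    0.5 * (1 + cos(pi * u / half))
  for (j in seq_along(ks)) {
    sh <- d_int + ks[j]           # y[t] = sum_k kern[k] x[t - d_int - k]
    if (sh >= n || kern[j] == 0) next
    if (sh >= 0) {
      out[(sh + 1):n] <- out[(sh + 1):n] + kern[j] * x[1:(n - sh)]
    } else {
      out[1:(n + sh)] <- out[1:(n + sh)] + kern[j] * x[(1 - sh):n]
    }
  }
  out
}

#' Simulate the multichannel recording of a scene
#'
#' Each channel receives every call delayed by its absolute run time
#' (fractional windowed-sinc interpolation), attenuated by
#' `ref_distance / |r_i|` under spherical spreading, plus independent white
#' Gaussian noise at `noise_spl` per channel.
#'
#' @param scene A `scene_spec`.
#' @param seed Integer seed for the noise.
#' @param pad Trailing silence in seconds after the last call.
#' @return A list with `rec` (a `multichannel_recording`: `samples` matrix
#'   n x M in Pa and `sample_rate`) and `truth` (tibble of per-call ground
#'   truth: call_id, emission, x, y, z, onset, duration, spl_at_array).
#' @export
simulate_scene <- function(scene, seed = 1, pad = 0.2) {
  fs <- scene$sample_rate
  calls <- scene$calls
  mics <- mic_matrix(scene$array)
  m <- nrow(mics)
  v <- scene$propagation$speed_of_sound
  spherical <- scene$propagation$attenuation == "spherical"

  ends <- vapply(seq_len(nrow(calls)), function(i) {
    calls$onset[i] + length(calls$call[[i]]$waveform) / fs
  }, numeric(1))
  max_run <- max(vapply(seq_len(nrow(calls)), function(i) {
    max(run_times(scene$array, c(calls$x[i], calls$y[i], calls$z[i]),
                  scene$propagation))
  }, numeric(1)))
  n <- ceiling((max(ends) + max_run + pad) * fs)
  x <- matrix(0, n, m)

  for (i in seq_len(nrow(calls))) {
    cl <- calls$call[[i]]
    if (cl$sample_rate != fs) {
      ratio <- cl$sample_rate / fs
      if (ratio >= 1 && abs(ratio - round(ratio)) < 1e-9) {
        wf <- signal::decimate(cl$waveform, round(ratio))
      } else {
        stop("call sample rate must equal the scene rate or be an integer multiple")
      }
    } else {
      wf <- cl$waveform
    }
    src <- c(wf, numeric(ceiling(max_run * fs) + 64))
    p <- c(calls$x[i], calls$y[i], calls$z[i])
    r <- sqrt(rowSums(sweep(mics, 2, p)^2))
    onset_smp <- round(calls$onset[i] * fs)
    for (j in seq_len(m)) {
      gain <- if (spherical) cl$ref_distance / r[j] else 1
      delayed <- fractional_delay(src, r[j] / v * fs) * gain
      idx <- onset_smp + seq_along(delayed)
      keep <- idx <= n & idx >= 1
      x[idx[keep], j] <- x[idx[keep], j] + delayed[keep]
    }
  }
  if (scene$noise_spl > -Inf) {
    n_rms <- db_to_pa(scene$noise_spl)
    x <- x + withr::with_seed(seed, matrix(rnorm(n * m, 0, n_rms), n, m))
  }
  truth <- tibble::tibble(
    call_id = calls$call_id %||% sprintf("call_%03d", seq_len(nrow(calls))),
    emission = calls$emission,
    x = calls$x, y = calls$y, z = calls$z,
    onset = calls$onset,
    duration = vapply(calls$call, function(cl)
      length(cl$waveform) / cl$sample_rate, numeric(1)),
    spl_at_array = vapply(calls$call, function(cl)
      cl$spec$spl_at_array %||% NA_real_, numeric(1))
  )
  list(
    rec = structure(list(samples = x, sample_rate = fs),
                    class = "multichannel_recording"),
    truth = truth
  )
}

#' @export
print.multichannel_recording <- function(x, ...) {
  cat(sprintf("<multichannel_recording: %d channels, %.2f s @ %d Hz>\n",
              ncol(x$samples), nrow(x$samples) / x$sample_rate, x$sample_rate))
  invisible(x)
}
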