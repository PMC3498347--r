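# Linear-prediction utilities shared by formant measurement and the
# spectral-descriptor pipeline.

#' Autocorrelation-method LPC coefficients
#'
#' @param x Waveform segment (mean is removed).
#' @param order Model order p.
#' @return List with `a` (coefficients `c(1, -a_1, ..., -a_p)` of the
#'   prediction-error filter) and `gain` (residual RMS gain).
#' @export
lpc_coeffs <- function(x, order) {
  x <- x - mean(x)
  n <- length(x)
  if (n <= order) stop("segment shorter than LPC order")
  nfft <- 2^ceiling(log2(2 * n))
  X <- fft(c(x, numeric(nfft - n)))
  r <- Re(fft(Mod(X)^2, inverse = TRUE)) / nfft
  r <- r[seq_len(order + 1)]
  if (r[1] <= 0) return(list(a = c(1, numeric(order)), gain = 0))
  R <- stats::toeplitz(r[seq_len(order)])
  diag(R) <- diag(R) * (1 + 1e-9)   # ridge against near-singular frames
  coef <- solve(R, r[2:(order + 1)])
  g2 <- r[1] - sum(coef * r[2:(order + 1)])
  list(a = c(1, -coef), gain = sqrt(max(g2, 0) / n))
}

#' LPC spectral envelope in dB
#'
#' @param lpc List from [lpc_coeffs()].
#' @param freqs Frequencies (Hz) at which to evaluate the envelope.
#' @param sample_rate Sampling rate of the analysed segment.
#' @return Envelope values 20*log10(gain / |A(e^-iw)|) in dB.
#' @export
lpc_envelope_db <- function(lpc, freqs, sample_rate) {
  p <- length(lpc$a) - 1
  w <- 2 * pi * freqs / sample_rate
  E <- exp(-1i * outer(w, 0:p))
  A <- as.vector(E %*% lpc$a)
  20 * log10(pmax(lpc$gain, 1e-12) / pmax(Mod(A), 1e-12))
}

#' Formant candidates from the roots of the LPC polynomial
#'
#' @param lpc List from [lpc_coeffs()].
#' @param sample_rate Sampling rate in Hz.
#' @param max_bw Maximum pole bandwidth in Hz for a root to count as a
#'   formant (default 150).
#' @return Tibble with `frequency` and `bandwidth` (Hz), sorted by
#'   frequency.
#' @export
lpc_formant_roots <- function(lpc, sample_rate, max_bw = 150) {
  rts <- polyroot(rev(lpc$a))
  ang <- Arg(rts)
  keep <- ang > 0 & ang < pi
  f <- ang[keep] * sample_rate / (2 * pi)
  bw <- -log(pmin(Mod(rts[keep]), 1)) * sample_rate / pi
  ok <- bw <= max_bw & f > 1
  out <- tibble::tibble(frequency = f[ok], bandwidth = bw[ok])
  out[order(out$frequency), ]
}

# resample to an integer target rate, decimating in stages of <= 10
resample_to <- function(x, fs, target) {
  if (fs == target) return(x)
  if (fs %% target == 0) {
    q <- fs %/% target
    while (q > 1) {
      step <- if (q <= 10) q else {
        cand <- which(q %% 2:10 == 0) + 1
        if (length(cand)) max(cand) else q
      }
      if (step > 13) stop("cannot decimate by prime factor > 13")
      x <- signal::decimate(x, step)
      q <- q %/% step
    }
    x
  } else {
    g <- gcd_int(fs, target)
    as.numeric(signal::resample(x, target / g, fs / g))
  }
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)
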