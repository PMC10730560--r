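# YIN fundamental-frequency estimator: difference function,
# cumulative-mean-normalized difference, absolute threshold, parabolic
# interpolation (the autocorrelation-based pitch tracker standard in voice
# analysis). FFT-accelerated difference function.

#' Estimate the fundamental frequency of a voiced signal (YIN)
#'
#' @param audio waveform (any calibration; the estimate is gain-invariant).
#' @param rate sampling rate, Hz; must exceed `2 * fmax`.
#' @param fmin,fmax search band, Hz (defaults 40-400, bracketing the
#'   replicas' 50-80 Hz oscillation range with margin).
#' @param threshold absolute threshold on the cumulative-mean-normalized
#'   difference. When no dip falls below it the estimator falls back to the
#'   global minimum of the normalized difference, provided that minimum is
#'   below `aperiodic_ceiling` (very noisy but still periodic signals);
#'   otherwise the signal is declared aperiodic.
#' @param aperiodic_ceiling normalized-difference level above which no
#'   periodicity is accepted (white noise sits near 1).
#' @return f0 in Hz, or `NA` for an aperiodic signal.
#' @export
#' @examples
#' t <- seq(0, 1, by = 1 / 8000)
#' estimate_f0(sin(2 * pi * 60 * t), 8000) # 60 Hz
estimate_f0 <- function(audio, rate, fmin = 40, fmax = 400,
                        threshold = 0.15, aperiodic_ceiling = 0.8) {
  if (rate <= 2 * fmax) stop("rate must exceed 2 * fmax")
  stopifnot(fmin > 0, fmax > fmin)
  x <- as.numeric(audio)
  n <- length(x)
  tau_min <- max(2L, floor(rate / fmax))
  tau_max <- ceiling(rate / fmin)
  if (n < ceiling(3 * rate / fmin))
    stop("window shorter than 3 periods of fmin")
  w <- min(n - tau_max, as.integer(rate)) # integration window, <= 1 s
  if (w < tau_max) stop("signal too short for the requested fmin")
  # difference function d(tau) = sum_{t=1..w} (x_t - x_{t+tau})^2
  # = S(0) + S(tau) - 2 r(tau), r via FFT cross-correlation
  seg <- x[seq_len(w + tau_max)]
  cs <- c(0, cumsum(seg^2))
  s0 <- cs[w + 1]
  s_tau <- cs[(w + 1):(w + tau_max + 1)] - cs[1:(tau_max + 1)]
  nfft <- 2^ceiling(log2(w + 2 * tau_max))
  fa <- fft(c(x[seq_len(w)], numeric(nfft - w)))
  fb <- fft(c(seg, numeric(nfft - w - tau_max)))
  r <- Re(fft(fb * Conj(fa), inverse = TRUE))[seq_len(tau_max + 1)] / nfft
  d <- s0 + s_tau - 2 * r
  d[1] <- 0
  tau <- seq_len(tau_max)
  dprime <- d[tau + 1] * tau / cumsum(d[tau + 1])
  dprime[cumsum(d[tau + 1]) == 0] <- 1
  # absolute-threshold search restricted to the band
  band <- tau_min:tau_max
  below <- band[dprime[band] < threshold]
  if (length(below) > 0) {
    k <- below[1]
    while (k < tau_max && dprime[k + 1] < dprime[k]) k <- k + 1L
  } else {
    k <- band[which.min(dprime[band])]
    if (dprime[k] >= aperiodic_ceiling) return(NA_real_)
  }
  # parabolic interpolation around the dip
  if (k > 1 && k < tau_max) {
    y1 <- dprime[k - 1]; y2 <- dprime[k]; y3 <- dprime[k + 1]
    denom <- y1 - 2 * y2 + y3
    delta <- if (denom != 0) 0.5 * (y1 - y3) / denom else 0
    delta <- max(-0.5, min(0.5, delta))
  } else delta <- 0
  f0 <- rate / (k + delta)
  if (f0 < fmin || f0 > fmax) return(NA_real_)
  f0
}
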