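# Reduction of raw bench time series (airflow, subglottal pressure,
# calibrated audio) to per-step aero-acoustic descriptors.

#' Detect quasi-steady airflow plateaus
#'
#' Decomposes a stepped-airflow record into maximal windows in which the
#' flow stays within `tol` (relative) of the window median for at least
#' `min_duration`. The trace is first block-averaged to about 50 Hz and
#' median-smoothed, plateaus are split at relative jumps larger than
#' `tol / 2`, and each candidate window is trimmed to its longest contiguous
#' run satisfying the median criterion.
#'
#' @param time sample times, s (uniform).
#' @param flow airflow, L/s.
#' @param min_duration minimum plateau length, s (default 3.5; bench steps
#'   last 4 s).
#' @param tol relative tolerance about the window median (default 5%).
#' @return data.frame of disjoint, ordered windows: `i_start`, `i_end`
#'   (sample indices), `t_start`, `t_end` (s). Empty (with a warning) when
#'   no plateau is found.
#' @export
segment_steps <- function(time, flow, min_duration = 3.5, tol = 0.05) {
  stopifnot(length(time) == length(flow), length(time) >= 2)
  dt <- time[2] - time[1]
  rate <- 1 / dt
  block <- max(1L, floor(rate / 50))
  nb <- floor(length(flow) / block)
  g <- colMeans(matrix(flow[seq_len(nb * block)], nrow = block))
  if (length(g) >= 5) g <- runmed(g, 5)
  dtb <- dt * block
  # split at relative jumps
  lev <- pmax(abs(g[-1]), abs(g[-length(g)]), 1e-12)
  brk <- which(abs(diff(g)) > pmax(0.5 * tol * lev, 1e-9))
  bounds <- c(0L, brk, length(g))
  windows <- list()
  for (s in seq_len(length(bounds) - 1L)) {
    lo <- bounds[s] + 1L; hi <- bounds[s + 1L]
    if ((hi - lo + 1L) * dtb < min_duration) next
    med <- median(g[lo:hi])
    ok <- abs(g[lo:hi] - med) <= tol * abs(med)
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    if (length(runs) == 0) next
    best <- runs[which.max(r$lengths[runs])]
    if (r$lengths[best] * dtb < min_duration) next
    b_lo <- lo + starts[best] - 1L
    b_hi <- lo + ends[best] - 1L
    i_start <- (b_lo - 1L) * block + 1L
    i_end <- min(length(flow), b_hi * block)
    windows[[length(windows) + 1L]] <-
      data.frame(i_start = i_start, i_end = i_end,
                 t_start = time[i_start], t_end = time[i_end])
  }
  if (length(windows) == 0) {
    warning("no quasi-steady window found")
    return(data.frame(i_start = integer(), i_end = integer(),
                      t_start = numeric(), t_end = numeric()))
  }
  do.call(rbind, windows)
}

#' Average aerodynamic state over a quasi-steady window
#'
#' Arithmetic means of flow and pressure over the window, plus the mean of
#' per-cycle pressure minima: with `f0` known, the window is divided into
#' consecutive oscillation cycles of length `1/f0` and the minimum of the
#' (lightly low-pass-filtered) pressure in each full cycle is located; the
#' mean of those minima is the cycle-resolved minimum pressure used as the
#' Bernoulli model input for maximal glottal areas.
#'
#' @param window one row of [segment_steps()] output (or any list with
#'   `i_start`, `i_end`).
#' @param time,flow,pressure the raw traces (s, L/s, Pa).
#' @param f0 oscillation fundamental, Hz, or `NA` (skips the cycle minima).
#' @param smooth_frac the pressure is moving-averaged over
#'   `smooth_frac / f0` seconds before the minima search, to keep wideband
#'   sensor noise from biasing per-cycle minima low; 0 disables.
#' @return list with `phi_mean` (L/s), `ps_mean` (Pa), `ps_min_cycle` (Pa,
#'   `NA` when `f0` is undefined or fewer than 3 full cycles fit).
#' @export
average_step <- function(window, time, flow, pressure, f0 = NA,
                         smooth_frac = 0.1) {
  i <- seq(window$i_start, window$i_end)
  if (length(i) == 0 || window$i_end < window$i_start)
    stop("empty averaging window")
  phi_mean <- mean(flow[i])
  ps_mean <- mean(pressure[i])
  ps_min_cycle <- NA_real_
  if (!is.na(f0) && f0 > 0) {
    dt <- time[2] - time[1]
    per <- 1 / f0
    n_cycles <- floor(length(i) * dt / per)
    if (n_cycles >= 3) {
      p <- pressure[i]
      if (smooth_frac > 0) {
        k <- max(1L, round(smooth_frac * per / dt))
        if (k > 1) p <- as.numeric(stats::filter(p, rep(1 / k, k),
                                                 sides = 2))
      }
      cyc <- floor((seq_along(i) - 1) * dt / per)
      keep <- cyc < n_cycles & !is.na(p)
      mins <- tapply(p[keep], cyc[keep], min)
      ps_min_cycle <- mean(mins)
    }
  }
  list(phi_mean = phi_mean, ps_mean = ps_mean, ps_min_cycle = ps_min_cycle)
}

#' Harmonic-to-noise ratio of a voiced signal
#'
#' Default method `"comb"`: the harmonic power is measured by Hann-windowed
#' projection on the first `max_harmonics` partials of `f0` (with `f0`
#' refined by maximizing that power, so partial drift over the window does
#' not leak harmonic energy into the noise estimate); the noise power is the
#' remainder of the total power, and `HNR = 10 log10(Ph / Pn)`.
#' Method `"acf"` is the classical normalized-autocorrelation estimator
#' `10 log10(r(T0) / (1 - r(T0)))` at the period lag (parabolic-interpolated
#' peak); it is simpler but noise-limited above roughly 30 dB.
#'
#' @param audio waveform.
#' @param rate sampling rate, Hz.
#' @param f0 fundamental frequency, Hz (from [estimate_f0()]).
#' @param method `"comb"` (default) or `"acf"`.
#' @param max_harmonics partials used by the comb method.
#' @param cap_db upper cap, dB (default +60; a noise-free signal reports the
#'   cap).
#' @return HNR in dB, capped at `cap_db`; `NA` when the signal is
#'   noise-dominated (non-positive periodicity evidence).
#' @export
compute_hnr <- function(audio, rate, f0, method = c("comb", "acf"),
                        max_harmonics = 30, cap_db = 60) {
  method <- match.arg(method)
  if (is.na(f0) || f0 <= 0) stop("f0 must be defined for HNR")
  x <- as.numeric(audio)
  n <- min(length(x), 2L * as.integer(rate)) # at most 2 s
  x <- x[seq_len(n)]
  if (method == "comb") {
    t <- (seq_len(n) - 1) / rate
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)) # Hann
    sw <- sum(w)
    K <- min(max_harmonics, floor((rate / 2) / f0) - 1L)
    if (K < 1) stop("rate too low for any harmonic of f0")
    harm_power <- function(f) {
      e1 <- exp(-2i * pi * f * t)
      cur <- rep(1 + 0i, n)
      ph <- 0
      for (k in seq_len(K)) {
        cur <- cur * e1
        ck <- 2 * sum(w * x * cur) / sw
        ph <- ph + Mod(ck)^2 / 2
      }
      ph
    }
    f_ref <- optimize(function(f) -harm_power(f),
                      interval = c(f0 - 0.3, f0 + 0.3), tol = 1e-4)$minimum
    ph <- harm_power(f_ref)
    ptot <- sum(w * x^2) / sw
    pn <- ptot - ph
    if (pn <= 0) return(cap_db)
    min(cap_db, 10 * log10(ph / pn))
  } else {
    tau0 <- rate / f0
    lags <- max(1L, floor(tau0) - 3L):min(n - 2L, ceiling(tau0) + 3L)
    r0 <- mean(x^2)
    r <- vapply(lags, function(l)
      sum(x[1:(n - l)] * x[(1 + l):n]) / (n - l), numeric(1)) / r0
    j <- which.max(r)
    if (j > 1 && j < length(r)) {
      y1 <- r[j - 1]; y2 <- r[j]; y3 <- r[j + 1]
      denom <- y1 - 2 * y2 + y3
      rmax <- if (denom != 0) y2 - (y1 - y3)^2 / (8 * denom) else y2
    } else rmax <- r[j]
    if (rmax <= 0) return(NA_real_)
    if (rmax >= 1) return(cap_db)
    min(cap_db, 10 * log10(rmax / (1 - rmax)))
  }
}

#' Measured glottal flow resistance
#'
#' `Rg = Ps / phi`: the overall mean translaryngeal pressure drop (taken
#' equal to the mean subglottal pressure) over the mean airflow.
#'
#' @param Ps_mean mean subglottal pressure, Pa.
#' @param phi_mean mean airflow, L/s (> 0).
#' @return resistance in Pa s/L (vectorized).
#' @export
glottal_resistance <- function(Ps_mean, phi_mean) {
  if (any(phi_mean <= 0)) stop("phi_mean must be positive")
  Ps_mean / phi_mean
}

#' Reduce one experimental round to a per-step descriptor table
#'
#' Runs the full reduction chain on raw traces: plateau detection
#' ([segment_steps()]), per-window averaging ([average_step()]), f0 by YIN
#' ([estimate_f0()]), SPL ([compute_spl()]), HNR ([compute_hnr()]) and
#' glottal resistance ([glottal_resistance()]). The audio and the
#' aerodynamic channels are assumed synchronous and equally sampled.
#'
#' @param time,flow,pressure raw traces (s, L/s, Pa).
#' @param audio calibrated microphone signal, Pa, same sampling as `time`.
#' @param rate sampling rate, Hz.
#' @param material,prestrain labels stored with the round (material name,
#'   anterior-posterior pre-strain `log(l / l0)`).
#' @param min_duration,tol plateau detection settings, see [segment_steps()].
#' @param fmin,fmax,yin_threshold YIN settings, see [estimate_f0()].
#' @param hnr_method HNR estimator, see [compute_hnr()].
#' @return data.frame with one row per quasi-steady step: `material`,
#'   `prestrain`, `t_start_s`, `t_end_s`, `phi_Ls`, `ps_Pa`, `ps_min_Pa`,
#'   `f0_Hz`, `spl_dB`, `hnr_dB`, `rg_PasL`, `ag_max_mm2` (NA, filled by the
#'   imaging stage).
#' @export
reduce_round <- function(time, flow, pressure, audio, rate,
                         material = "synthetic", prestrain = 0,
                         min_duration = 3.5, tol = 0.05, fmin = 40,
                         fmax = 400, yin_threshold = 0.15,
                         hnr_method = "comb") {
  win <- segment_steps(time, flow, min_duration = min_duration, tol = tol)
  if (nrow(win) == 0)
    return(data.frame(material = character(), prestrain = numeric(),
                      t_start_s = numeric(), t_end_s = numeric(),
                      phi_Ls = numeric(), ps_Pa = numeric(),
                      ps_min_Pa = numeric(), f0_Hz = numeric(),
                      spl_dB = numeric(), hnr_dB = numeric(),
                      rg_PasL = numeric(), ag_max_mm2 = numeric()))
  steps <- lapply(seq_len(nrow(win)), function(s) {
    w <- win[s, ]
    i <- seq(w$i_start, w$i_end)
    a <- audio[i]
    f0 <- tryCatch(estimate_f0(a, rate, fmin, fmax, yin_threshold),
                   error = function(e) NA_real_)
    avg <- average_step(w, time, flow, pressure, f0 = f0)
    spl <- compute_spl(a)
    hnr <- if (!is.na(f0)) compute_hnr(a, rate, f0, method = hnr_method)
           else NA_real_
    data.frame(material = material, prestrain = prestrain,
               t_start_s = w$t_start, t_end_s = w$t_end,
               phi_Ls = avg$phi_mean, ps_Pa = avg$ps_mean,
               ps_min_Pa = avg$ps_min_cycle, f0_Hz = f0, spl_dB = spl,
               hnr_dB = hnr,
               rg_PasL = glottal_resistance(avg$ps_mean, avg$phi_mean),
               ag_max_mm2 = NA_real_)
  })
  out <- do.call(rbind, steps)
  out[order(out$phi_Ls), , drop = FALSE]
}
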