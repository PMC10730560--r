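# Synthetic aerodynamic and acoustic time series with known ground truth.

#' Generate a stepped flow/pressure protocol
#'
#' Piecewise-constant airflow plateaus of `step_duration` each, with mean
#' subglottal pressure following the linear law
#' `Ps = true_Rd * phi + true_P0`, a sinusoidal ripple at `f0_true`
#' (amplitude `ripple_frac` of the plateau mean, capped at 20%), and Gaussian
#' measurement noise on both channels.
#'
#' @param cfg a [bench_config()].
#' @return list with `time` (s), `flow_Ls`, `pressure_Pa`, and `truth`, a
#'   data.frame of per-plateau ground truth (`step`, `t_start`, `t_end`,
#'   `phi_Ls`, `ps_mean_Pa`, `ps_min_Pa` = mean minus ripple amplitude).
#' @export
#' @examples
#' cfg <- bench_config(flow_steps = 1, audio_rate = 4000, noise_sd_flow = 0,
#'                     noise_sd_pressure = 0, ripple_frac = 0)
#' mean(gen_flow_pressure(cfg)$pressure_Pa) # 530 * 1 + 800 = 1330 Pa
gen_flow_pressure <- function(cfg) {
  stopifnot(inherits(cfg, "bench_config"))
  if (length(cfg$flow_steps) == 0) stop("no protocol: flow_steps is empty")
  set.seed(cfg$seed)
  rate <- cfg$audio_rate
  n_per <- round(cfg$step_duration * rate)
  n_steps <- length(cfg$flow_steps)
  n <- n_per * n_steps
  time <- (seq_len(n) - 1) / rate
  flow <- rep(cfg$flow_steps, each = n_per)
  ps_mean <- cfg$true_Rd * flow + cfg$true_P0
  ripple_amp <- cfg$ripple_frac * ps_mean
  pressure <- ps_mean + ripple_amp * sin(2 * pi * cfg$f0_true * time)
  if (cfg$noise_sd_flow > 0) flow <- flow + rnorm(n, 0, cfg$noise_sd_flow)
  if (cfg$noise_sd_pressure > 0)
    pressure <- pressure + rnorm(n, 0, cfg$noise_sd_pressure)
  mu <- cfg$true_Rd * cfg$flow_steps + cfg$true_P0
  truth <- data.frame(
    step = seq_len(n_steps),
    t_start = (seq_len(n_steps) - 1) * cfg$step_duration,
    t_end = seq_len(n_steps) * cfg$step_duration,
    phi_Ls = cfg$flow_steps,
    ps_mean_Pa = mu,
    ps_min_Pa = mu * (1 - cfg$ripple_frac))
  list(time = time, flow_Ls = flow, pressure_Pa = pressure, truth = truth)
}

#' Synthesize a calibrated voice-like waveform
#'
#' Harmonic series at `f0` (amplitudes 1/k over `n_harmonics` partials) plus
#' white Gaussian noise. The noise is rescaled to its realized sample RMS so
#' the harmonic-to-noise power ratio equals `hnr_db` exactly, then the mix is
#' rescaled so the total RMS matches `spl_db` re 20 uPa exactly; both
#' realized values are returned as ground truth.
#'
#' @param f0 fundamental frequency, Hz (40-400).
#' @param duration length of the synthesized segment, s.
#' @param rate sampling rate, Hz.
#' @param spl_db target sound pressure level, dB re 20 uPa.
#' @param hnr_db target harmonic-to-noise ratio, dB; `Inf` for a noiseless
#'   periodic signal. Values above 60 dB are allowed but flagged with a
#'   warning (the noise floor falls below measurement precision).
#' @param n_harmonics number of partials.
#' @return list with `wave` (Pa), `harmonic`, `noise` (the two scaled
#'   components), `rate`, and realized `spl_db`, `hnr_db`.
#' @export
synth_voice <- function(f0, duration, rate = 22050, spl_db = 70,
                        hnr_db = 20, n_harmonics = 20) {
  stopifnot(f0 >= 40, f0 <= 400, duration > 0)
  if (rate <= 2 * n_harmonics * f0)
    stop("rate must exceed twice the highest harmonic")
  if (is.finite(hnr_db) && hnr_db > 60)
    warning("hnr_db > 60 dB: noise floor below measurement precision")
  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / rate
  harm <- rep(0, n)
  for (k in seq_len(n_harmonics)) harm <- harm + sin(2 * pi * k * f0 * t) / k
  harm <- harm / sqrt(mean(harm^2)) # unit RMS
  if (is.finite(hnr_db)) {
    noise <- rnorm(n)
    noise <- noise / sqrt(mean(noise^2)) * 10^(-hnr_db / 20)
  } else {
    noise <- rep(0, n)
  }
  wave <- harm + noise
  target_rms <- P_REF * 10^(spl_db / 20)
  s <- target_rms / sqrt(mean(wave^2))
  harm <- harm * s
  noise <- noise * s
  wave <- wave * s
  hnr_real <- if (all(noise == 0)) Inf else
    10 * log10(mean(harm^2) / mean(noise^2))
  list(wave = wave, harmonic = harm, noise = noise, rate = rate,
       spl_db = 20 * log10(sqrt(mean(wave^2)) / P_REF), hnr_db = hnr_real)
}

#' Generate bench audio from a configuration
#'
#' Wrapper around [synth_voice()] that takes targets from a [bench_config()].
#'
#' @param cfg a [bench_config()].
#' @param duration segment length, s; defaults to one step duration.
#' @param spl_db,hnr_db overrides for the config targets.
#' @return see [synth_voice()].
#' @export
gen_audio <- function(cfg, duration = cfg$step_duration,
                      spl_db = cfg$spl_true, hnr_db = cfg$hnr_true) {
  stopifnot(inherits(cfg, "bench_config"))
  set.seed(cfg$seed + 1L)
  synth_voice(cfg$f0_true, duration, rate = cfg$audio_rate, spl_db = spl_db,
              hnr_db = hnr_db, n_harmonics = cfg$n_harmonics)
}

#' Generate a per-step summary table directly (no time series)
#'
#' Draws per-plateau mean pressures from `Ps = Rd * phi + P0 + N(0, sd)`.
#' Lightweight counterpart of [gen_flow_pressure()] for simulation studies of
#' the phenomenological fits, where full 22 kHz traces are unnecessary.
#'
#' @param phi airflow plateau values, L/s.
#' @param Rd,P0 generating law coefficients, Pa s/L and Pa.
#' @param noise_sd pressure noise SD per step, Pa.
#' @param spl_law optional `c(k, l)` for an SPL column
#'   `k * log10(phi) + l` (no noise).
#' @return data.frame with `phi_Ls`, `ps_Pa`, `rg_PasL` and optionally
#'   `spl_dB`.
#' @export
gen_step_table <- function(phi = seq(0.4, 3.4, length.out = 10), Rd = 530,
                           P0 = 800, noise_sd = 50, spl_law = NULL) {
  stopifnot(all(phi > 0))
  ps <- Rd * phi + P0 + rnorm(length(phi), 0, noise_sd)
  out <- data.frame(phi_Ls = phi, ps_Pa = ps, rg_PasL = ps / phi)
  if (!is.null(spl_law)) out$spl_dB <- spl_law[1] * log10(phi) + spl_law[2]
  out
}
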