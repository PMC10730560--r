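#' Synthetic bench configuration
#'
#' Collects every constant of the emulated phonation bench: acquisition rates
#' and image geometry (22.05 kHz sampling, 1473 frames/s high-speed video,
#' 736 x 1296 px frames at 123 px/cm), the stepped-airflow protocol (4 s
#' quasi-steady plateaus from about 0.3 to 3.5 L/s), the linear pressure-flow
#' law `Ps = true_Rd * phi + true_P0` the bench obeys on average, and the
#' source characteristics of the synthesized voice signal (f0, SPL, HNR, open
#' quotient, lower/upper margin phase delay).
#'
#' @param seed integer seed; every random draw of the generators derives from
#'   it.
#' @param audio_rate audio/pressure/flow sampling rate, Hz.
#' @param video_rate high-speed camera frame rate, frames/s.
#' @param image_size frame size, `c(rows, cols)` px.
#' @param px_per_cm image calibration, px/cm.
#' @param step_duration duration of one quasi-steady airflow plateau, s.
#' @param flow_steps airflow plateau values, L/s, strictly increasing.
#' @param true_Rd,true_P0 differentiated glottal resistance (Pa s/L) and
#'   extrapolated pressure intercept (Pa) of the generating linear
#'   pressure-flow law.
#' @param f0_true oscillation fundamental, Hz (40-400).
#' @param hnr_true harmonic-to-noise ratio of the synthesized audio, dB
#'   (`Inf` disables the noise branch).
#' @param spl_true sound pressure level of single-segment audio, dB re 20 uPa.
#' @param spl_law optional `c(k, l)`: per-step SPL follows
#'   `k * log10(phi) + l`, mimicking the logarithmic SPL-flow relation of a
#'   real bench. Used by [run_synthetic_study()]; `NULL` keeps `spl_true`
#'   for all steps.
#' @param oq_true open quotient of the glottal area waveform, in (0, 1].
#' @param phase_delay lag of the left fold margin behind the right one, s
#'   (produces the diamond-shaped aperture of a physiological mucosal wave).
#' @param glottal_length_mm fold length at rest along the anterior-posterior
#'   axis, mm.
#' @param n_harmonics number of harmonics in the synthesized voice source.
#' @param ripple_frac relative amplitude of the sinusoidal pressure ripple at
#'   `f0_true` riding on each plateau (must stay <= 0.2).
#' @param noise_sd_pressure,noise_sd_flow Gaussian measurement-noise standard
#'   deviations, Pa and L/s.
#' @return an object of class `bench_config` (a validated list).
#' @export
bench_config <- function(seed = 1L,
                         audio_rate = 22050,
                         video_rate = 1473,
                         image_size = c(736, 1296),
                         px_per_cm = 123,
                         step_duration = 4,
                         flow_steps = seq(0.3, 3.5, length.out = 10),
                         true_Rd = 530,
                         true_P0 = 800,
                         f0_true = 60,
                         hnr_true = 20,
                         spl_true = 70,
                         spl_law = c(k = 15, l = 70),
                         oq_true = 0.6,
                         phase_delay = 0,
                         glottal_length_mm = 20,
                         n_harmonics = 20,
                         ripple_frac = 0.10,
                         noise_sd_pressure = 20,
                         noise_sd_flow = 0.02) {
  cfg <- list(seed = as.integer(seed), audio_rate = audio_rate,
              video_rate = video_rate, image_size = image_size,
              px_per_cm = px_per_cm, step_duration = step_duration,
              flow_steps = flow_steps, true_Rd = true_Rd, true_P0 = true_P0,
              f0_true = f0_true, hnr_true = hnr_true, spl_true = spl_true,
              spl_law = spl_law, oq_true = oq_true, phase_delay = phase_delay,
              glottal_length_mm = glottal_length_mm,
              n_harmonics = n_harmonics, ripple_frac = ripple_frac,
              noise_sd_pressure = noise_sd_pressure,
              noise_sd_flow = noise_sd_flow)
  class(cfg) <- "bench_config"
  validate_bench_config(cfg)
}

validate_bench_config <- function(cfg) {
  stopifnot(inherits(cfg, "bench_config"))
  with(cfg, {
    if (length(flow_steps) > 0 && any(diff(flow_steps) <= 0))
      stop("flow_steps must be strictly increasing")
    if (!(oq_true > 0 && oq_true <= 1)) stop("oq_true must be in (0, 1]")
    if (audio_rate <= 2 * n_harmonics * f0_true)
      stop("audio_rate must exceed twice the highest synthesized harmonic (",
           n_harmonics * f0_true, " Hz)")
    if (step_duration <= 3 / f0_true)
      stop("step_duration must exceed 3 cycles of f0_true")
    if (ripple_frac < 0 || ripple_frac > 0.2)
      stop("ripple_frac must be in [0, 0.2]")
    stopifnot(video_rate > 0, px_per_cm > 0, length(image_size) == 2,
              all(image_size > 0), glottal_length_mm > 0,
              noise_sd_pressure >= 0, noise_sd_flow >= 0)
  })
  cfg
}

#' @export
print.bench_config <- function(x, ...) {
  cat("<bench_config>\n")
  cat(sprintf("  audio %g Hz | video %g fps | %d x %d px at %g px/cm\n",
              x$audio_rate, x$video_rate, x$image_size[1], x$image_size[2],
              x$px_per_cm))
  cat(sprintf("  protocol: %d flow steps in [%g, %g] L/s, %g s each\n",
              length(x$flow_steps), min(x$flow_steps), max(x$flow_steps),
              x$step_duration))
  cat(sprintf("  law: Ps = %g * phi + %g Pa | f0 %g Hz | HNR %g dB\n",
              x$true_Rd, x$true_P0, x$f0_true, x$hnr_true))
  invisible(x)
}
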