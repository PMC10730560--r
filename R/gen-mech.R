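# Synthetic quasi-static mechanical test records with known constitutive law.

#' Generate a cyclic tensile (or shear/compression) record
#'
#' Emulates a quasi-static cyclic test: `n_cycles` load-unload cycles with
#' peak strains equally spaced up to `eps_max`, at constant strain rate
#' `rate`, sampled uniformly in time. Stress follows a known law:
#' linear `P = E * eps` or exponential `P = a * (exp(b * eps) - 1)`, with an
#' optional multiplicative hysteresis softening on the unloading paths.
#'
#' @param law `"linear"` or `"exponential"`.
#' @param params named coefficients: `E` (MPa) for linear; `a` (MPa), `b`
#'   for exponential.
#' @param n_cycles number of cycles (>= 1).
#' @param eps_max peak strain of the last cycle (the bench protocol reaches
#'   0.7 over 4 cycles).
#' @param rate strain rate, 1/s (bench: 1e-2).
#' @param sample_rate sampling rate of the record, Hz.
#' @param hysteresis unloading stress is `(1 - hysteresis)` times the loading
#'   law at the same strain; 0 disables.
#' @param noise_sd Gaussian stress noise SD, MPa.
#' @param mode channel labels: `"tension"`, `"compression"` or `"shear"`.
#' @return a `stress_strain_record`: list with `time` (s), `strain`, `stress`
#'   (MPa), `mode`, `cycles` (ground-truth segment index ranges, see
#'   [segment_cycles()]) and `truth` (law, params, peak strains).
#' @export
#' @examples
#' rec <- gen_tensile("linear", c(E = 0.02), n_cycles = 4, eps_max = 0.7)
#' max(rec$stress) # 0.02 * 0.7 = 0.014 MPa
gen_tensile <- function(law = c("linear", "exponential"), params,
                        n_cycles = 4, eps_max = 0.7, rate = 1e-2,
                        sample_rate = 2, hysteresis = 0, noise_sd = 0,
                        mode = c("tension", "compression", "shear")) {
  law <- match.arg(law)
  mode <- match.arg(mode)
  stopifnot(eps_max > 0, n_cycles >= 1, rate > 0, sample_rate > 0,
            hysteresis >= 0, hysteresis < 1)
  peaks <- eps_max * seq_len(n_cycles) / n_cycles
  # triangular strain path: 0 -> peak1 -> 0 -> peak2 -> 0 ...
  knots_eps <- c(0, as.vector(rbind(peaks, 0)))
  knots_t <- c(0, cumsum(abs(diff(knots_eps)) / rate))
  time <- seq(0, max(knots_t), by = 1 / sample_rate)
  strain <- stats::approx(knots_t, knots_eps, xout = time)$y
  stress_law <- switch(law,
    linear = function(e) params[["E"]] * e,
    exponential = function(e) params[["a"]] * (exp(params[["b"]] * e) - 1))
  stress <- stress_law(strain)
  # segment boundaries at the knots
  knot_idx <- vapply(knots_t, function(tt) which.min(abs(time - tt)),
                     integer(1))
  cycles <- lapply(seq_len(n_cycles), function(i) {
    list(load = c(knot_idx[2 * i - 1], knot_idx[2 * i]),
         unload = c(knot_idx[2 * i], knot_idx[2 * i + 1]),
         peak_strain = peaks[i])
  })
  if (hysteresis > 0) {
    for (cy in cycles) {
      idx <- seq(cy$unload[1] + 1L, cy$unload[2])
      stress[idx] <- stress[idx] * (1 - hysteresis)
    }
  }
  if (noise_sd > 0) stress <- stress + rnorm(length(stress), 0, noise_sd)
  structure(list(time = time, strain = strain, stress = stress, mode = mode,
                 cycles = cycles,
                 truth = list(law = law, params = params, peaks = peaks)),
            class = "stress_strain_record")
}

#' Generate a synthetic adhesion (tack) trace
#'
#' Emulates the plate-contact adhesion protocol: compression to a fixed
#' strain, a stress-relaxation hold during which the force settles at
#' `f_relax`, then a pull-off during which the force resisting separation
#' peaks and decays exponentially with time constant `tack_tau` (tackier
#' surfaces decay slower, separating later).
#'
#' @param f_relax force level during the relaxation hold, N.
#' @param peak_force pull-off force peak, N.
#' @param tack_tau decay time constant of the pull-off force, s.
#' @param relax_duration hold duration, s (bench: 180 s).
#' @param compress_duration,pull_duration ramp and pull lengths, s.
#' @param sample_rate sampling rate, Hz.
#' @param noise_sd force noise SD, N.
#' @return list with `time` (s), `force` (N), `relax_window` (c(start, end)
#'   s) and `truth` (parameters, including the analytic separation delay
#'   `tack_tau * log(20)` after the peak, where the force drops to 5%).
#' @export
gen_adhesion <- function(f_relax = 2, peak_force = 1, tack_tau = 3,
                         relax_duration = 180, compress_duration = 20,
                         pull_duration = 60, sample_rate = 10,
                         noise_sd = 0) {
  stopifnot(f_relax > 0, peak_force > 0, tack_tau > 0)
  t_total <- compress_duration + relax_duration + pull_duration
  time <- seq(0, t_total, by = 1 / sample_rate)
  force <- numeric(length(time))
  # compression ramp down to -1.5 * f_relax then exponential settling
  ramp <- time <= compress_duration
  force[ramp] <- -1.5 * f_relax * time[ramp] / compress_duration
  hold <- time > compress_duration & time <= compress_duration + relax_duration
  th <- time[hold] - compress_duration
  force[hold] <- -f_relax - 0.5 * f_relax * exp(-th / 10)
  pull <- time > compress_duration + relax_duration
  tp <- time[pull] - (compress_duration + relax_duration)
  rise <- 1 # s to reach the pull-off peak
  force[pull] <- ifelse(tp <= rise, peak_force * tp / rise,
                        peak_force * exp(-(tp - rise) / tack_tau))
  if (noise_sd > 0) force <- force + rnorm(length(force), 0, noise_sd)
  relax_window <- c(compress_duration + relax_duration / 2,
                    compress_duration + relax_duration)
  list(time = time, force = force, relax_window = relax_window,
       truth = list(f_relax = f_relax, peak_force = peak_force,
                    tack_tau = tack_tau,
                    t_peak = compress_duration + relax_duration + rise,
                    separation_delay = tack_tau * log(20)))
}
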