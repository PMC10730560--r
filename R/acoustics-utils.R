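#' Speed of sound in air
#'
#' Ideal-gas approximation `c = 331.3 * sqrt(1 + T/273.15)` m/s, adequate for
#' room-temperature duct acoustics.
#'
#' @param temp_c air temperature in degrees Celsius (default 22, the bench's
#'   room temperature).
#' @return speed of sound in m/s.
#' @export
#' @examples
#' speed_of_sound(22) # about 344 m/s
speed_of_sound <- function(temp_c = 22) {
  331.3 * sqrt(1 + temp_c / 273.15)
}

#' Resonance frequencies of an open-closed tube
#'
#' Quarter-wave resonances `f_n = (2n - 1) c / (4 L)` of a duct closed at one
#' end (the glottis) and open at the other (the settling chamber). Used to
#' estimate the first acoustic resonance of the subglottal tract and check
#' whether it can interfere with the vocal-fold oscillation frequency.
#'
#' @param length_m tube length in m.
#' @param temp_c air temperature in degrees Celsius.
#' @param n resonance order(s), 1 = fundamental.
#' @return resonance frequency in Hz (vectorized over `n`).
#' @export
#' @examples
#' tube_resonance(6.2) # about 14 Hz for the bench's 6.2 m supply line
tube_resonance <- function(length_m, temp_c = 22, n = 1) {
  stopifnot(length_m > 0, all(n >= 1))
  (2 * n - 1) * speed_of_sound(temp_c) / (4 * length_m)
}

#' Cross-sectional area of a circular duct
#'
#' @param diameter_m inner diameter in m.
#' @return area in m^2. The bench's 2 cm tracheal inlet tube gives
#'   3.14e-4 m^2 (3.14 cm^2).
#' @export
circle_area <- function(diameter_m) {
  stopifnot(all(diameter_m > 0))
  pi * (diameter_m / 2)^2
}

# interface unit conversions: flows L/s <-> m^3/s, areas mm^2 <-> m^2
ls_to_m3s <- function(phi_Ls) phi_Ls * 1e-3
m3s_to_ls <- function(phi_m3s) phi_m3s * 1e3
mm2_to_m2 <- function(a_mm2) a_mm2 * 1e-6
m2_to_mm2 <- function(a_m2) a_m2 * 1e6

#' Sound pressure level of a calibrated waveform
#'
#' Unweighted SPL: `20 log10(rms / 20 uPa)` of a calibrated acoustic pressure
#' signal in Pa.
#'
#' @param audio calibrated pressure samples, Pa.
#' @return SPL in dB re 20 uPa, or `NA` for a silent input (with a warning).
#' @export
#' @examples
#' x <- sqrt(2) * sin(2 * pi * 60 * seq(0, 1, by = 1 / 8000)) # RMS 1 Pa
#' compute_spl(x) # 93.98 dB
compute_spl <- function(audio) {
  rms <- sqrt(mean(audio^2))
  if (rms == 0) {
    warning("silent input: SPL undefined")
    return(NA_real_)
  }
  20 * log10(rms / P_REF)
}
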