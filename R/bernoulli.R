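# Quasi-steady Bernoulli glottal-flow model with the Liljencrants
# flow-separation criterion (A_sep ~ 1.2 * A_g). Internally SI (Pa, m^3/s,
# m^2); interfaces take L/s and mm^2, the units of bench instrumentation.

#' Parameters of the quasi-steady Bernoulli glottal-flow model
#'
#' @param rho air density, kg/m^3 (1.20 at 22 C).
#' @param A_s tracheal cross-section where subglottal pressure is measured,
#'   m^2 (3.14e-4, a 2 cm diameter tube).
#' @param sep_coeff Liljencrants separation coefficient linking the jet
#'   separation area to the glottal area, `A_sep = sep_coeff * A_g`
#'   (>= 1, default 1.2).
#' @return object of class `bernoulli_params`.
#' @export
bernoulli_params <- function(rho = 1.20, A_s = 3.14e-4, sep_coeff = 1.2) {
  stopifnot(rho > 0, A_s > 0, sep_coeff >= 1)
  structure(list(rho = rho, A_s = A_s, sep_coeff = sep_coeff),
            class = "bernoulli_params")
}

#' @export
print.bernoulli_params <- function(x, ...) {
  cat(sprintf("<bernoulli_params> rho = %g kg/m^3, A_s = %g m^2, A_sep = %g Ag\n",
              x$rho, x$A_s, x$sep_coeff))
  invisible(x)
}

#' Predict glottal area from subglottal pressure and airflow
#'
#' Inverts the quasi-steady Bernoulli balance between the tracheal section
#' and the jet separation point:
#' `Ag = (1/sep_coeff) * (2 Ps / (rho phi^2) + 1 / A_s^2)^(-1/2)`.
#' Strictly decreasing in `Ps`, increasing in `phi`; at `Ps = 0` it returns
#' the duct area divided by the separation coefficient.
#'
#' @param Ps subglottal pressure, Pa (>= 0).
#' @param phi airflow, L/s (> 0).
#' @param params a [bernoulli_params()].
#' @return glottal area in mm^2 (vectorized).
#' @export
#' @examples
#' predict_area(1000, 1) # about 20.35 mm^2
predict_area <- function(Ps, phi, params = bernoulli_params()) {
  stopifnot(inherits(params, "bernoulli_params"))
  if (any(Ps < 0)) stop("Ps must be non-negative")
  if (any(phi == 0 & Ps > 0)) stop("undefined jet: phi = 0 with Ps > 0")
  if (any(phi <= 0)) stop("phi must be positive")
  q <- ls_to_m3s(phi)
  ag_m2 <- (1 / params$sep_coeff) *
    (2 * Ps / (params$rho * q^2) + 1 / params$A_s^2)^(-1 / 2)
  m2_to_mm2(ag_m2)
}

#' Glottal flow resistance predicted by the Bernoulli model
#'
#' `Rg = (rho / 2) * phi * (1/(sep_coeff * Ag)^2 - 1/A_s^2)`, i.e. the model
#' pressure divided by the flow; [predict_pressure()] is defined as
#' `predict_resistance() * phi` so the identity is exact by construction.
#'
#' @param Ag glottal area, mm^2 (> 0).
#' @inheritParams predict_area
#' @return resistance in Pa s/L (vectorized). Values <= 0 (when
#'   `sep_coeff * Ag >= A_s`, outside the model's validity) are returned
#'   with a warning.
#' @export
predict_resistance <- function(Ag, phi, params = bernoulli_params()) {
  stopifnot(inherits(params, "bernoulli_params"))
  if (any(Ag <= 0)) stop("Ag must be positive")
  if (any(phi <= 0)) stop("phi must be positive")
  a_sep <- params$sep_coeff * mm2_to_m2(Ag)
  if (any(a_sep >= params$A_s))
    warning("sep_coeff * Ag >= A_s: model outside validity, Ps <= 0")
  q <- ls_to_m3s(phi)
  rg_si <- 0.5 * params$rho * q * (1 / a_sep^2 - 1 / params$A_s^2)
  rg_si / 1e3 # Pa s/m^3 -> Pa s/L
}

#' Predict subglottal pressure from glottal area and airflow
#'
#' Exact inverse of [predict_area()]:
#' `Ps = (rho/2) phi^2 (1/(sep_coeff * Ag)^2 - 1/A_s^2)`.
#'
#' @inheritParams predict_resistance
#' @return pressure in Pa (vectorized).
#' @export
#' @examples
#' predict_pressure(predict_area(1000, 1), 1) # 1000 Pa
predict_pressure <- function(Ag, phi, params = bernoulli_params()) {
  predict_resistance(Ag, phi, params) * phi
}

#' Iso-resistance abacus of the Bernoulli model
#'
#' For each requested glottal resistance, solves
#' `predict_resistance(Ag, phi) = Rg` for `Ag` over a flow grid. A closed
#' form exists (the relation is monotone in `Ag`); each solution is
#' cross-checked by monotone root bracketing and against
#' [predict_resistance()] to `tol` relative. Curves increase with flow and
#' are ordered: higher resistance, smaller area.
#'
#' @param Rg_values resistances, Pa s/L (> 0); the bench abacuses span 50 to
#'   40000.
#' @param phi_grid airflow grid, L/s (> 0).
#' @param params a [bernoulli_params()].
#' @param tol relative self-consistency tolerance.
#' @return data.frame with `rg_PasL`, `phi_Ls`, `ag_mm2`. Grid points with
#'   no admissible solution are omitted (with a message).
#' @export
abacus <- function(Rg_values, phi_grid, params = bernoulli_params(),
                   tol = 1e-9) {
  stopifnot(all(Rg_values > 0), all(phi_grid > 0))
  out <- list()
  for (rg in Rg_values) {
    q <- ls_to_m3s(phi_grid)
    rhs <- 2 * (rg * 1e3) / (params$rho * q) + 1 / params$A_s^2
    ag_m2 <- 1 / (params$sep_coeff * sqrt(rhs))
    ag <- m2_to_mm2(ag_m2)
    # bracketing cross-check of the closed form
    ok <- vapply(seq_along(ag), function(i) {
      f <- function(a) predict_resistance(a, phi_grid[i], params) - rg
      lo <- ag[i] * 0.5; hi <- min(ag[i] * 2, m2_to_mm2(params$A_s) /
                                     params$sep_coeff * (1 - 1e-12))
      if (f(lo) < 0 || f(hi) > 0) return(FALSE)
      root <- uniroot(f, c(lo, hi), tol = ag[i] * 1e-12)$root
      abs(root - ag[i]) <= tol * ag[i] &&
        abs(predict_resistance(ag[i], phi_grid[i], params) - rg) <= tol * rg
    }, logical(1))
    if (!all(ok))
      message(sum(!ok), " abacus point(s) without admissible solution at Rg = ",
              rg, " Pa s/L; omitted")
    out[[length(out) + 1L]] <- data.frame(rg_PasL = rg,
                                          phi_Ls = phi_grid[ok],
                                          ag_mm2 = ag[ok])
  }
  do.call(rbind, out)
}
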