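# Phenomenological models fitted to per-step descriptors:
#   Ps  = Rd * phi + P0          (linear pressure-flow law)
#   Rg  = P0 / phi + Rd          (the same law divided by phi)
#   SPL = k * log10(phi or Ps) + l

new_fit_result <- function(model, coefficients, standard_errors, residual_sd,
                           n_points) {
  structure(list(model = model, coefficients = coefficients,
                 standard_errors = standard_errors,
                 residual_sd = residual_sd, n_points = n_points),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", x$model, sprintf("(n = %d)\n", x$n_points))
  co <- rbind(estimate = x$coefficients, se = x$standard_errors)
  print(round(co, 4))
  invisible(x)
}

fit_steps_ols <- function(y, xpred, model, coef_names, weights = NULL) {
  n <- length(y)
  if (n < 3) stop("at least 3 steps required for a 2-parameter fit")
  if (length(unique(signif(xpred, 12))) < 2)
    stop("degenerate predictor: all steps identical")
  fit <- if (is.null(weights)) lm(y ~ xpred) else
    lm(y ~ xpred, weights = weights)
  s <- summary(fit)
  co <- c(coef(fit)[2], coef(fit)[1])
  se <- c(s$coefficients[2, 2], s$coefficients[1, 2])
  names(co) <- names(se) <- coef_names
  new_fit_result(model, co, se, s$sigma, n)
}

#' Fit the linear pressure-flow law Ps = Rd * phi + P0
#'
#' Ordinary least squares of mean subglottal pressure on mean airflow across
#' the quasi-steady steps of a round. The slope is the differentiated
#' glottal resistance `Rd` (Pa s/L), the intercept the extrapolated pressure
#' `P0` (Pa); standard errors come from the residual variance.
#'
#' @param steps data.frame with columns `phi_Ls` and `ps_Pa` (e.g. from
#'   [reduce_round()] or [gen_step_table()]).
#' @param weights optional OLS weights.
#' @return a `fit_result` with coefficients `Rd`, `P0`.
#' @export
fit_pressure_flow <- function(steps, weights = NULL) {
  fit_steps_ols(steps$ps_Pa, steps$phi_Ls, "pressure_flow_linear",
                c("Rd", "P0"), weights)
}

#' Fit the hyperbolic resistance law Rg = P0 / phi + Rd
#'
#' Least squares of per-step glottal resistance on inverse airflow. For data
#' satisfying `Ps = Rd * phi + P0` exactly this returns the same `(Rd, P0)`
#' as [fit_pressure_flow()] (the two models are the same law divided by
#' `phi`); on noisy data the two fits weight the steps differently.
#'
#' @param steps data.frame with `phi_Ls` and `rg_PasL` (or `ps_Pa`, from
#'   which `Rg = Ps / phi` is computed).
#' @param weights optional OLS weights.
#' @return a `fit_result` with coefficients `Rd` (intercept) and `P0`
#'   (slope on `1/phi`).
#' @export
fit_resistance <- function(steps, weights = NULL) {
  rg <- if (!is.null(steps$rg_PasL)) steps$rg_PasL else
    glottal_resistance(steps$ps_Pa, steps$phi_Ls)
  r <- fit_steps_ols(rg, 1 / steps$phi_Ls, "resistance_hyperbolic",
                     c("P0", "Rd"), weights)
  # report in the (Rd, P0) order used everywhere else
  r$coefficients <- r$coefficients[c("Rd", "P0")]
  r$standard_errors <- r$standard_errors[c("Rd", "P0")]
  r
}

#' Fit the logarithmic SPL law SPL = k log10(x) + l
#'
#' OLS of SPL on `log10` of the chosen predictor (airflow or subglottal
#' pressure). Steps with non-positive predictor values are excluded with a
#' warning.
#'
#' @param steps data.frame with `spl_dB` and `phi_Ls` or `ps_Pa`.
#' @param predictor `"flow"` or `"pressure"`.
#' @param weights optional OLS weights.
#' @return a `fit_result` with coefficients `k` (dB per decade) and `l`
#'   (dB).
#' @export
fit_spl_log <- function(steps, predictor = c("flow", "pressure"),
                        weights = NULL) {
  predictor <- match.arg(predictor)
  x <- if (predictor == "flow") steps$phi_Ls else steps$ps_Pa
  keep <- is.finite(x) & x > 0 & is.finite(steps$spl_dB)
  if (any(x <= 0, na.rm = TRUE))
    warning("non-positive predictor values excluded from the SPL fit")
  fit_steps_ols(steps$spl_dB[keep], log10(x[keep]),
                paste0("spl_log_", predictor), c("k", "l"),
                if (!is.null(weights)) weights[keep] else NULL)
}
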