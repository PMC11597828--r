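#' Bioavailable fraction from a single zero-order stage (closed form)
#'
#' For a drug with one-compartment disposition absorbed in a single
#' zero-order stage of duration tau, the bioavailable fraction follows
#' from the ratio of the oral AUC to the AUC of the hypothetical IV bolus
#' obtained by back-extrapolating the post-absorption elimination phase:
#' `F = kel * tau / (exp(kel * tau) - 1)`. F is strictly decreasing in
#' the product `kel * tau` and tends to 1 as absorption becomes
#' instantaneous.
#'
#' @param kel Elimination rate constant (1/hour), > 0.
#' @param tau Duration of drug absorption (hours), > 0.
#' @return A `bioavailability_estimate` (method `"eq3"`).
#' @examples
#' estimate_F_eq3(kel = 1, tau = 1)$value      # 0.582
#' estimate_F_eq3(kel = 0.64, tau = 0.75)$value
#' @export
estimate_F_eq3 <- function(kel, tau) {
  kel <- check_scalar_pos(kel, "kel")
  tau <- check_scalar_pos(tau, "tau")
  x <- kel * tau
  value <- x / expm1(x)
  new_F_estimate(value, "eq3", list(kel = kel, tau = tau))
}

#' Bioavailable fraction from two zero-order stages (closed form)
#'
#' Extension of the single-stage closed form to two successive zero-order
#' input stages under one-compartment disposition. With stage amounts
#' `a_i = F_i D / Vd` (rate times duration, concentration scale),
#' `F = (a1 + a2) kel / [ (a1/tau1)(e^{kel tau1} - 1) +
#'      (a2/tau2) e^{kel tau1} (e^{kel tau2} - 1) ]`.
#' With `a2 = 0` it reduces to the single-stage form at `tau1`; with
#' equal stage rates it reduces to the single-stage form at
#' `tau1 + tau2`.
#'
#' @param amount1,amount2 Stage amounts on the concentration scale
#'   (rate x duration), >= 0, not both zero.
#' @param tau1,tau2 Stage durations (hours), > 0.
#' @param kel Elimination rate constant (1/hour), > 0.
#' @return A `bioavailability_estimate` (method `"eq4"`).
#' @examples
#' estimate_F_eq4(0.00816, 0.00143, 1.2, 1.3, kel = 0.12)$value
#' @export
estimate_F_eq4 <- function(amount1, amount2, tau1, tau2, kel) {
  amount1 <- check_scalar_pos(amount1, "amount1", strict = FALSE)
  amount2 <- check_scalar_pos(amount2, "amount2", strict = FALSE)
  tau1 <- check_scalar_pos(tau1, "tau1")
  tau2 <- check_scalar_pos(tau2, "tau2")
  kel <- check_scalar_pos(kel, "kel")
  if (amount1 == 0 && amount2 == 0)
    stop_pbftpk("at least one stage amount must be positive")
  denom <- amount1 / tau1 * expm1(kel * tau1) +
    amount2 / tau2 * exp(kel * tau1) * expm1(kel * tau2)
  value <- (amount1 + amount2) * kel / denom
  new_F_estimate(value, "eq4",
                 list(amount1 = amount1, amount2 = amount2,
                      tau1 = tau1, tau2 = tau2, kel = kel))
}

#' Log-linear fit of the terminal elimination phase
#'
#' Ordinary least squares of log concentration on time over every
#' observation strictly later than the absorption cutoff `tau`; the
#' intercept, reported back on the concentration scale at t = 0, is the
#' back-extrapolated concentration of the hypothetical IV bolus.
#' Nonpositive concentrations among the qualifying points are excluded
#' with a warning; at least three usable points are required.
#'
#' @param series A [conc_series()].
#' @param tau Absorption cutoff (hours): only observations with
#'   `time > tau` enter the fit.
#' @return A `terminal_phase_fit` object: `kel_hat` (1/hour), `intercept`
#'   (concentration at t = 0), `t_start`, `n_points`, `r_squared`.
#' @examples
#' ts <- 4:12
#' ser <- conc_series(ts, 2 * exp(-0.3 * ts))
#' terminal_phase_fit(ser, tau = 3)
#' @export
terminal_phase_fit <- function(series, tau) {
  stopifnot(inherits(series, "conc_series"))
  tau <- check_scalar_pos(tau, "tau")
  sel <- series$times > tau
  if (sum(sel) < 3L)
    stop_pbftpk(sprintf(
      "terminal-phase fit needs at least 3 observations after tau = %g h, got %d",
      tau, sum(sel)))
  t <- series$times[sel]
  y <- series$concentrations[sel]
  if (any(y <= 0)) {
    warning(sprintf("%d nonpositive concentration(s) after tau excluded from terminal fit",
                    sum(y <= 0)), call. = FALSE)
    t <- t[y > 0]
    y <- y[y > 0]
    if (length(t) < 3L)
      stop_pbftpk(sprintf(
        "terminal-phase fit needs at least 3 positive observations after tau, got %d",
        length(t)))
  }
  fit <- lm(log(y) ~ t)
  slope <- unname(coef(fit)[2L])
  if (!is.finite(slope) || slope >= 0)
    stop_pbftpk("terminal phase is not declining; cannot estimate kel")
  # computed directly: summary.lm() warns on numerically perfect fits
  ly <- log(y)
  sst <- sum((ly - mean(ly))^2)
  r2 <- if (sst <= 0) 1 else 1 - sum(fit$residuals^2) / sst
  structure(list(kel_hat = -slope,
                 intercept = unname(exp(coef(fit)[1L])),
                 t_start = t[1L],
                 n_points = length(t),
                 r_squared = r2),
            class = "terminal_phase_fit")
}

#' @export
print.terminal_phase_fit <- function(x, ...) {
  cat(sprintf("<terminal_phase_fit> kel = %.4g /h, C0 = %.4g, %d points (t >= %g h), r2 = %.4f\n",
              x$kel_hat, x$intercept, x$n_points, x$t_start, x$r_squared))
  invisible(x)
}

#' AUC by linear trapezoid with exponential tail
#'
#' Linear trapezoidal quadrature over the observed range plus the
#' standard extrapolated tail `C_last / kel_hat`.
#'
#' @param series A [conc_series()] with at least two points.
#' @param kel_hat Terminal elimination rate constant (1/hour), > 0.
#' @return AUC from the first observation to infinity
#'   (concentration x hours).
#' @examples
#' auc_trapezoid_with_tail(conc_series(c(0, 1), c(0, 1)), kel_hat = 1)  # 1.5
#' @export
auc_trapezoid_with_tail <- function(series, kel_hat) {
  stopifnot(inherits(series, "conc_series"))
  kel_hat <- check_scalar_pos(kel_hat, "kel_hat")
  t <- series$times
  y <- series$concentrations
  if (length(t) < 2L)
    stop_pbftpk("AUC requires at least two observations")
  sum(diff(t) * (y[-1L] + y[-length(y)]) / 2) + y[length(y)] / kel_hat
}

#' Fraction of dose absorbed by the semi-noncompartmental AUC ratio
#'
#' Estimates the fraction of dose absorbed F* exclusively from oral data:
#' the terminal phase beyond the absorption cutoff tau is back-
#' extrapolated to a hypothetical IV bolus with
#' `AUC_hyp_iv = intercept / kel_hat`, the oral AUC is computed by
#' trapezoid-plus-tail using the same `kel_hat`, and
#' `F* = (AUC_oral / AUC_hyp_iv) ^ exponent`. The default exponent is
#' 1/2; `exponent = 1` gives the plain AUC ratio, which on
#' model-consistent data coincides with the closed forms
#' [estimate_F_eq3()] / [estimate_F_eq4()]. When no first-pass effect
#' operates, F* equals the bioavailable fraction F.
#'
#' @param series A [conc_series()].
#' @param tau Absorption cutoff (hours) for the terminal-phase fit.
#' @param exponent Exponent applied to the AUC ratio.
#' @return A `bioavailability_estimate` (method `"eq5"`) whose
#'   `inputs_used` records both AUCs, the terminal-fit parameters, and
#'   `exponent_used`.
#' @examples
#' m <- pbftpk_model(absorption_schedule(1, 1), one_compartment(1))
#' ts <- seq(0.05, 12, by = 0.05)
#' ser <- conc_series(ts, concentration(m, ts))
#' estimate_F_star_eq5(ser, tau = 1, exponent = 1)$value  # ~0.582
#' @export
estimate_F_star_eq5 <- function(series, tau, exponent = 0.5) {
  stopifnot(inherits(series, "conc_series"))
  if (!is.numeric(exponent) || length(exponent) != 1L || !is.finite(exponent) ||
      exponent <= 0)
    stop_pbftpk("'exponent' must be a single positive number")
  tp <- terminal_phase_fit(series, tau)
  auc_iv <- tp$intercept / tp$kel_hat
  stopifnot(auc_iv > 0)
  auc_oral <- auc_trapezoid_with_tail(series, tp$kel_hat)
  if (auc_oral <= 0) stop_pbftpk("oral AUC is not positive")
  value <- (auc_oral / auc_iv)^exponent
  est <- new_F_estimate(value, "eq5",
                        list(tau = tau, kel_hat = tp$kel_hat,
                             intercept = tp$intercept,
                             auc_oral = auc_oral, auc_hyp_iv = auc_iv))
  est$exponent_used <- exponent
  est
}

new_F_estimate <- function(value, method, inputs_used) {
  if (!is.finite(value) || value <= 0)
    stop_pbftpk("bioavailability estimate is not positive; check inputs")
  structure(list(value = value, method = method, inputs_used = inputs_used,
                 exponent_used = NA_real_),
            class = "bioavailability_estimate")
}

#' @export
print.bioavailability_estimate <- function(x, ...) {
  cat(sprintf("<bioavailability_estimate> %s: %.4f\n", x$method, x$value))
  invisible(x)
}
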