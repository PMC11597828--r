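#' Closed-form concentration for zero-order input into one compartment
#'
#' Central concentration for a schedule of successive zero-order input
#' stages with first-order elimination. The solution superposes shifted
#' constant-rate infusion responses: stage i with rate r_i running on
#' (b_{i-1}, b_i] contributes
#' `r_i/kel * [(1 - e^{-kel (t - b_{i-1})})_+ - (1 - e^{-kel (t - b_i)})_+]`.
#' The curve is continuous, starts at `C(0) = 0`, and decays as
#' `C(tau) e^{-kel (t - tau)}` once absorption has terminated at the
#' finite absorption time tau.
#'
#' @param schedule An [absorption_schedule()].
#' @param disposition A [one_compartment()] object.
#' @param t Vector of times in hours, all >= 0.
#' @return Numeric vector of concentrations, same length as `t`.
#' @examples
#' sch <- absorption_schedule(1, 1)
#' concentration_one_compartment(sch, one_compartment(1), c(0, 1, 2))
#' @export
concentration_one_compartment <- function(schedule, disposition, t) {
  stopifnot(inherits(schedule, "absorption_schedule"),
            inherits(disposition, "one_compartment"))
  check_times(t)
  kel <- disposition$kel
  starts <- c(0, head(schedule$breakpoints, -1L))
  ends <- schedule$breakpoints
  ramp <- function(x) ifelse(x > 0, 1 - exp(-kel * x), 0)
  C <- numeric(length(t))
  for (i in seq_along(ends)) {
    C <- C + schedule$stages$rate[i] / kel *
      (ramp(t - starts[i]) - ramp(t - ends[i]))
  }
  pmax(C, 0)
}

#' Closed-form concentration for zero-order input into two compartments
#'
#' Central-compartment concentration of the linear two-compartment system
#' (micro-constants k12, k21, k10) driven by a piecewise-constant input
#' rate, zero after the last stage. Built from the unit-impulse response
#' of the central compartment,
#' `h(t) = A e^{-alpha t} + B e^{-beta t}` with
#' `A = (alpha - k21)/(alpha - beta)` and `B = (k21 - beta)/(alpha - beta)`,
#' integrated over each start/stop pair. Terminal decay is governed by the
#' slower hybrid constant beta.
#'
#' @param schedule An [absorption_schedule()].
#' @param disposition A [two_compartment()] object.
#' @param t Vector of times in hours, all >= 0.
#' @return Numeric vector of concentrations, same length as `t`.
#' @examples
#' sch <- absorption_schedule(2, 1)
#' concentration_two_compartment(sch, two_compartment(0.5, 0.3, 0.2), c(0, 1, 2, 6))
#' @export
concentration_two_compartment <- function(schedule, disposition, t) {
  stopifnot(inherits(schedule, "absorption_schedule"),
            inherits(disposition, "two_compartment"))
  check_times(t)
  a <- disposition$alpha
  b <- disposition$beta
  A <- (a - disposition$k21) / (a - b)
  B <- (disposition$k21 - b) / (a - b)
  # integral of h from 0 to x (unit-rate infusion step response)
  stepr <- function(x) ifelse(x > 0,
                              A * (1 - exp(-a * x)) / a +
                              B * (1 - exp(-b * x)) / b, 0)
  starts <- c(0, head(schedule$breakpoints, -1L))
  ends <- schedule$breakpoints
  C <- numeric(length(t))
  for (i in seq_along(ends)) {
    C <- C + schedule$stages$rate[i] *
      (stepr(t - starts[i]) - stepr(t - ends[i]))
  }
  pmax(C, 0)
}

#' Bateman function
#'
#' Classical first-order absorption / first-order elimination curve,
#' `C(t) = scale * ka/(ka - kel) * (e^{-kel t} - e^{-ka t})`.
#'
#' @param model A [bateman_model()].
#' @param t Vector of times in hours, all >= 0.
#' @return Numeric vector of concentrations.
#' @examples
#' bateman_concentration(bateman_model(2, 0.5, 1), c(0, 0.5, 1, 4))
#' @export
bateman_concentration <- function(model, t) {
  stopifnot(inherits(model, "bateman_model"))
  check_times(t)
  with(model, pmax(scale * ka / (ka - kel) * (exp(-kel * t) - exp(-ka * t)), 0))
}

#' Model concentration at given times
#'
#' Dispatches to the closed-form simulator matching the model's
#' disposition (or to the Bateman function).
#'
#' @param model A [pbftpk_model()] or [bateman_model()].
#' @param t Vector of times in hours, all >= 0.
#' @return Numeric vector of concentrations.
#' @export
concentration <- function(model, t) UseMethod("concentration")

#' @export
concentration.pbftpk_model <- function(model, t) {
  if (inherits(model$disposition, "one_compartment"))
    concentration_one_compartment(model$schedule, model$disposition, t)
  else
    concentration_two_compartment(model$schedule, model$disposition, t)
}

#' @export
concentration.bateman_model <- function(model, t) bateman_concentration(model, t)

#' Analytic area under the curve to infinity
#'
#' For a PBFTPK model the total amount delivered per central volume is
#' `sum(r_i tau_i)`, and mass balance gives
#' `AUC = sum(r_i tau_i) / kel` (one compartment) or
#' `AUC = sum(r_i tau_i) / k10` (two compartments).
#'
#' @param model A [pbftpk_model()].
#' @return AUC from zero to infinity (concentration x hours).
#' @examples
#' auc_infinity_analytic(pbftpk_model(absorption_schedule(1, 1), one_compartment(1)))
#' @export
auc_infinity_analytic <- function(model) {
  stopifnot(inherits(model, "pbftpk_model"))
  total <- sum(model$schedule$stages$amount)
  kout <- if (inherits(model$disposition, "one_compartment"))
    model$disposition$kel else model$disposition$k10
  total / kout
}

#' Peak concentration and time of peak
#'
#' For one-compartment disposition the concentration is monotone within
#' each input stage (relaxing toward r_i/kel) and decays after the last,
#' so the maximum lies exactly at a stage breakpoint; it is located by
#' direct evaluation. In particular a single-stage model peaks exactly at
#' the finite absorption time. For two-compartment disposition the peak is
#' found by a dense grid search refined with local optimization.
#'
#' @param model A [pbftpk_model()].
#' @return Named numeric vector `c(cmax = ..., tmax = ...)`.
#' @examples
#' cmax_tmax(pbftpk_model(absorption_schedule(1, 1), one_compartment(1)))
#' @export
cmax_tmax <- function(model) {
  stopifnot(inherits(model, "pbftpk_model"))
  tau <- model$schedule$total_duration
  if (inherits(model$disposition, "one_compartment")) {
    cand <- c(0, model$schedule$breakpoints)
    Cc <- concentration(model, cand)
    i <- which.max(Cc)
    return(c(cmax = Cc[i], tmax = cand[i]))
  }
  slow <- model$disposition$beta
  horizon <- tau + 2 / slow
  grid <- seq(0, horizon, length.out = 2001L)
  Cg <- concentration(model, grid)
  i <- which.max(Cg)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  opt <- optimize(function(x) concentration(model, x),
                  interval = c(lo, hi), maximum = TRUE, tol = 1e-10)
  if (opt$objective >= Cg[i])
    c(cmax = opt$objective, tmax = opt$maximum)
  else
    c(cmax = Cg[i], tmax = grid[i])
}

check_times <- function(t) {
  if (!is.numeric(t) || length(t) == 0L || !all(is.finite(t)))
    stop_pbftpk("'t' must be a non-empty finite numeric vector")
  if (any(t < 0)) stop_pbftpk("negative times are not allowed")
  invisible(t)
}
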