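#' Concentration-time series
#'
#' Container for an observed or simulated oral concentration-time profile.
#' Times are in hours since dose administration; concentrations are in the
#' declared unit and never converted silently.
#'
#' @param times Numeric vector of sampling times (hours), strictly
#'   increasing, first value >= 0.
#' @param concentrations Numeric vector of concentrations (>= 0), same
#'   length as `times`.
#' @param unit_label Concentration unit as text, e.g. `"mg/mL"` or
#'   `"ng/mL"`.
#' @param label Text identifier for the series.
#'
#' @return An object of class `conc_series` with fields `times`,
#'   `concentrations`, `unit_label`, `label`.
#' @examples
#' conc_series(c(0, 1, 2, 4), c(0, 0.8, 0.5, 0.2), "mg/mL", "example")
#' @export
conc_series <- function(times, concentrations, unit_label = "mg/mL",
                        label = "series") {
  if (!is.numeric(times) || !is.numeric(concentrations))
    stop_pbftpk("'times' and 'concentrations' must be numeric")
  if (length(times) != length(concentrations))
    stop_pbftpk(sprintf(
      "lengths differ: %d times vs %d concentrations",
      length(times), length(concentrations)))
  if (length(times) == 0L) stop_pbftpk("series must contain at least one point")
  if (!all(is.finite(times)) || !all(is.finite(concentrations)))
    stop_pbftpk("all times and concentrations must be finite")
  if (times[1L] < 0) stop_pbftpk("first time must be >= 0")
  if (any(diff(times) <= 0)) {
    bad <- which(diff(times) <= 0)[1L] + 1L
    stop_pbftpk(sprintf("times must be strictly increasing (violated at point %d)", bad))
  }
  if (any(concentrations < 0)) stop_pbftpk("concentrations must be >= 0")
  structure(
    list(times = as.numeric(times),
         concentrations = as.numeric(concentrations),
         unit_label = as.character(unit_label)[1L],
         label = as.character(label)[1L]),
    class = "conc_series")
}

#' @export
print.conc_series <- function(x, ...) {
  cat(sprintf("<conc_series> '%s': %d points over %g h, unit %s\n",
              x$label, length(x$times), max(x$times), x$unit_label))
  invisible(x)
}

#' @export
as.data.frame.conc_series <- function(x, ...) {
  data.frame(time = x$times, concentration = x$concentrations)
}

#' @export
length.conc_series <- function(x) length(x$times)

#' Absorption schedule of successive zero-order input stages
#'
#' Under the finite absorption time premise, oral input proceeds as one or
#' more successive constant-rate (zero-order) stages; absorption terminates
#' at the end of the last stage. Each stage i has a duration tau_i (h) and
#' an input rate r_i expressed on the concentration scale (concentration
#' per hour, i.e. the composite F_i.D/Vd divided by tau_i), so
#' `rate * duration` is a concentration-scale amount.
#'
#' @param durations Numeric vector of stage durations in hours, all > 0.
#'   Length 1 to 3 is typical; any positive length is accepted.
#' @param rates Numeric vector of stage input rates (concentration/hour),
#'   all >= 0, same length as `durations`.
#'
#' @return An object of class `absorption_schedule` with fields `stages`
#'   (data frame: duration, rate, amount), `total_duration` (the finite
#'   absorption time tau), and `breakpoints` (cumulative stage end times).
#' @examples
#' sch <- absorption_schedule(c(4.2, 3.2, 4.2), c(0.0009, 0.0024, 0.0016))
#' sch$total_duration   # 11.6
#' @export
absorption_schedule <- function(durations, rates) {
  if (!is.numeric(durations) || !is.numeric(rates))
    stop_pbftpk("'durations' and 'rates' must be numeric")
  if (length(durations) != length(rates))
    stop_pbftpk("'durations' and 'rates' must have equal length")
  if (length(durations) < 1L) stop_pbftpk("at least one stage is required")
  if (!all(is.finite(durations)) || !all(is.finite(rates)))
    stop_pbftpk("stage parameters must be finite")
  if (any(durations <= 0)) stop_pbftpk("all stage durations must be > 0")
  if (any(rates < 0)) stop_pbftpk("all stage rates must be >= 0")
  durations <- as.numeric(durations)
  rates <- as.numeric(rates)
  structure(
    list(stages = data.frame(duration = durations, rate = rates,
                             amount = rates * durations),
         total_duration = sum(durations),
         breakpoints = cumsum(durations)),
    class = "absorption_schedule")
}

#' @export
print.absorption_schedule <- function(x, ...) {
  cat(sprintf("<absorption_schedule> %d stage(s), total duration %g h\n",
              nrow(x$stages), x$total_duration))
  print(x$stages)
  invisible(x)
}

#' One-compartment disposition
#'
#' First-order elimination from a single (central) compartment.
#'
#' @param kel Elimination rate constant (1/hour), > 0.
#' @return An object of class `c("one_compartment", "disposition")`.
#' @examples
#' one_compartment(0.12)
#' @export
one_compartment <- function(kel) {
  structure(list(kel = check_scalar_pos(kel, "kel")),
            class = c("one_compartment", "disposition"))
}

#' Two-compartment disposition (micro-constants)
#'
#' Central and peripheral compartments with first-order transfer and
#' elimination from the central compartment. Parametrized by the
#' micro-constants k12 (central to peripheral), k21 (peripheral to
#' central) and k10 (elimination), all in 1/hour. The hybrid constants
#' alpha > beta > 0 follow from positivity of the micro-constants (the
#' discriminant is strictly positive whenever k12 > 0).
#'
#' @param k12,k21,k10 Micro rate constants (1/hour), all > 0.
#' @return An object of class `c("two_compartment", "disposition")` with
#'   derived fields `alpha` and `beta`.
#' @examples
#' d <- two_compartment(0.6, 0.4, 0.1)
#' c(d$alpha, d$beta)
#' @export
two_compartment <- function(k12, k21, k10) {
  k12 <- check_scalar_pos(k12, "k12")
  k21 <- check_scalar_pos(k21, "k21")
  k10 <- check_scalar_pos(k10, "k10")
  s <- k12 + k21 + k10
  disc <- sqrt(s^2 - 4 * k21 * k10)
  structure(list(k12 = k12, k21 = k21, k10 = k10,
                 alpha = (s + disc) / 2, beta = (s - disc) / 2),
            class = c("two_compartment", "disposition"))
}

#' PBFTPK model: absorption schedule plus disposition
#'
#' A physiologically based finite-time pharmacokinetic model: n successive
#' zero-order input stages feeding a one- or two-compartment disposition.
#'
#' @param schedule An [absorption_schedule()].
#' @param disposition A [one_compartment()] or [two_compartment()] object.
#' @return An object of class `pbftpk_model`.
#' @examples
#' m <- pbftpk_model(absorption_schedule(1, 1), one_compartment(1))
#' concentration(m, c(0, 0.5, 1, 2))
#' @export
pbftpk_model <- function(schedule, disposition) {
  if (!inherits(schedule, "absorption_schedule"))
    stop_pbftpk("'schedule' must be an absorption_schedule")
  if (!inherits(disposition, "disposition"))
    stop_pbftpk("'disposition' must be a one_compartment or two_compartment object")
  structure(list(schedule = schedule, disposition = disposition),
            class = "pbftpk_model")
}

#' @export
print.pbftpk_model <- function(x, ...) {
  dtype <- if (inherits(x$disposition, "one_compartment"))
    "one-compartment" else "two-compartment"
  cat(sprintf("<pbftpk_model> %d input stage(s), %s disposition, tau = %g h\n",
              nrow(x$schedule$stages), dtype, x$schedule$total_duration))
  invisible(x)
}

#' Bateman (first-order absorption) comparator model
#'
#' The classical one-compartment curve with first-order absorption and
#' elimination, `C(t) = scale * ka/(ka - kel) * (exp(-kel t) - exp(-ka t))`,
#' where `scale` houses the composite F.D_po/Vd. It implies absorption of
#' infinite duration and serves only as a comparator to the finite-time
#' models. The degenerate case ka == kel is rejected.
#'
#' @param ka First-order absorption rate constant (1/hour), > 0.
#' @param kel First-order elimination rate constant (1/hour), > 0,
#'   different from `ka`.
#' @param scale Concentration-scale amplitude (F.D_po/Vd), > 0.
#' @return An object of class `bateman_model`.
#' @examples
#' bateman_model(ka = 2, kel = 0.5, scale = 1)
#' @export
bateman_model <- function(ka, kel, scale) {
  ka <- check_scalar_pos(ka, "ka")
  kel <- check_scalar_pos(kel, "kel")
  scale <- check_scalar_pos(scale, "scale")
  if (ka == kel)
    stop_pbftpk("degenerate Bateman model with ka == kel is not supported")
  structure(list(ka = ka, kel = kel, scale = scale), class = "bateman_model")
}

#' @export
print.bateman_model <- function(x, ...) {
  cat(sprintf("<bateman_model> ka = %g /h, kel = %g /h, scale = %g\n",
              x$ka, x$kel, x$scale))
  invisible(x)
}
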