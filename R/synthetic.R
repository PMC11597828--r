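#' Measurement noise model for simulated profiles
#'
#' Combined proportional and additive Gaussian noise with an optional
#' limit of quantification, emulating assay error plus the error
#' introduced when concentration-time points are read off published
#' figures. Identical seeds give identical draws.
#'
#' @param proportional_cv Coefficient of variation of the proportional
#'   error component (fraction, >= 0).
#' @param additive_sd Standard deviation of the additive component
#'   (concentration units, >= 0).
#' @param loq Limit of quantification (concentration units, >= 0);
#'   simulated values below it are handled per `loq_action`.
#' @param loq_action `"drop"` (default) removes sub-LOQ points;
#'   `"zero"` reports them as zero.
#' @param seed Integer seed for the draws.
#' @return An object of class `noise_model`.
#' @examples
#' noise_model(proportional_cv = 0.05, seed = 42)
#' @export
noise_model <- function(proportional_cv = 0, additive_sd = 0, loq = 0,
                        loq_action = c("drop", "zero"), seed = 1L) {
  structure(list(
    proportional_cv = check_scalar_pos(proportional_cv, "proportional_cv",
                                       strict = FALSE),
    additive_sd = check_scalar_pos(additive_sd, "additive_sd", strict = FALSE),
    loq = check_scalar_pos(loq, "loq", strict = FALSE),
    loq_action = match.arg(loq_action),
    seed = as.integer(seed)),
    class = "noise_model")
}

#' Simulate a noisy oral concentration-time profile
#'
#' Evaluates the forward model at the sampling times and applies the
#' noise model: `C_obs = max(0, C_true * (1 + e_p) + e_a)` with
#' `e_p ~ N(0, cv^2)` and `e_a ~ N(0, sd^2)`, then the LOQ rule.
#' With zero noise the output equals the forward model exactly.
#'
#' @param model A [pbftpk_model()] (or [bateman_model()]).
#' @param sampling_times Strictly increasing sampling times (hours).
#' @param noise A [noise_model()].
#' @param unit_label,label Passed to the returned [conc_series()].
#' @return A [conc_series()].
#' @examples
#' m <- pbftpk_model(absorption_schedule(0.75, 0.031), one_compartment(0.64))
#' generate_profile(m, c(0.25, 0.5, 1, 2, 4, 8),
#'                  noise_model(proportional_cv = 0.05, seed = 7))
#' @export
generate_profile <- function(model, sampling_times, noise = noise_model(),
                             unit_label = "mg/mL", label = "simulated") {
  stopifnot(inherits(model, "pbftpk_model") || inherits(model, "bateman_model"),
            inherits(noise, "noise_model"))
  if (length(sampling_times) == 0L)
    stop_pbftpk("sampling schedule must not be empty")
  check_times(sampling_times)
  if (any(diff(sampling_times) <= 0))
    stop_pbftpk("sampling times must be strictly increasing")
  ctrue <- concentration(model, sampling_times)
  n <- length(sampling_times)
  draws <- with_seed(noise$seed, list(
    ep = rnorm(n, 0, noise$proportional_cv),
    ea = rnorm(n, 0, noise$additive_sd)))
  obs <- pmax(0, ctrue * (1 + draws$ep) + draws$ea)
  t <- sampling_times
  if (noise$loq > 0) {
    below <- obs < noise$loq
    if (noise$loq_action == "drop") {
      t <- t[!below]
      obs <- obs[!below]
      if (length(t) == 0L)
        stop_pbftpk("all simulated observations fall below the LOQ")
    } else {
      obs[below] <- 0
    }
  }
  conc_series(t, obs, unit_label = unit_label, label = label)
}

# Study templates: absorption schedules (durations h, rates conc/h) are the
# fitted values reported for each formulation; disposition constants and
# sampling schedules are NOT reported there and are synthetic, literature-
# plausible choices (see the methods vignette).
.templates <- list(
  ketoprofen_like = list(
    durations = 0.75, rates = 0.031,
    disposition = function() one_compartment(0.64),
    sampling = c(0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 5, 6, 8),
    unit = "mg/mL"),
  amlodipine_like = list(
    durations = c(2.1, 5.3), rates = c(1.16, 0.80),
    disposition = function() two_compartment(0.08, 0.05, 0.04),
    sampling = c(1, 2, 3, 4, 5, 6, 8, 10, 12, 16, 24, 36, 48, 72, 96),
    unit = "ng/mL"),
  theophylline_ir_like = list(
    durations = c(1.20, 1.3), rates = c(0.0068, 0.0011),
    disposition = function() one_compartment(0.12),
    sampling = c(0.25, 0.5, 1, 1.5, 2, 2.5, 3, 4, 6, 8, 12, 16, 24),
    unit = "mg/mL"),
  theotrim_like = list(
    durations = c(0.72, 6.28), rates = c(0.0018, 0.0007),
    disposition = function() one_compartment(0.07),
    sampling = c(0.5, 1, 2, 3, 4, 5, 6, 7, 8, 10, 12, 16, 24, 32),
    unit = "mg/mL"),
  theodur_like = list(
    durations = c(4.2, 3.2, 4.2), rates = c(0.0009, 0.0024, 0.0016),
    disposition = function() one_compartment(0.09),
    sampling = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 14, 16, 20, 24, 32, 40),
    unit = "mg/mL"),
  levonorgestrel_like = list(
    durations = 1.09, rates = 8.3,
    disposition = function() two_compartment(0.6, 0.4, 0.1),
    sampling = c(0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8, 12, 24, 36, 48),
    unit = "ng/mL")
)

#' Names of the built-in study templates
#' @return Character vector of template names.
#' @export
list_templates <- function() names(.templates)

#' Retrieve a built-in study template
#'
#' Each template bundles a ground-truth PBFTPK model (absorption schedule
#' from published fitted values; synthetic, literature-plausible
#' disposition constants) and a typical clinical sampling schedule,
#' dense early and sparse late.
#'
#' @param name One of [list_templates()].
#' @return A `study_template` list: `name`, `model`, `sampling_times`,
#'   `unit_label`.
#' @examples
#' study_template("theodur_like")$model
#' @export
study_template <- function(name) {
  if (!is.character(name) || length(name) != 1L || !(name %in% names(.templates)))
    stop_pbftpk("unknown template '", paste(name, collapse = ","),
                "'; valid names: ", paste(names(.templates), collapse = ", "))
  tp <- .templates[[name]]
  structure(list(
    name = name,
    model = pbftpk_model(absorption_schedule(tp$durations, tp$rates),
                         tp$disposition()),
    sampling_times = tp$sampling,
    unit_label = tp$unit),
    class = "study_template")
}

#' Simulated study fixture with known ground truth
#'
#' Generates a (possibly noisy) profile from a named template and returns
#' it together with its ground-truth model, closing the loop for
#' simulate-then-fit round trips.
#'
#' @param name One of [list_templates()].
#' @param noise A [noise_model()].
#' @return A list with `series` (a [conc_series()]), `model` (the truth),
#'   and `template` (the name).
#' @examples
#' fx <- study_fixture("ketoprofen_like", noise_model())
#' fx$model$schedule$total_duration   # 0.75
#' @export
study_fixture <- function(name, noise = noise_model()) {
  tp <- study_template(name)
  series <- generate_profile(tp$model, tp$sampling_times, noise,
                             unit_label = tp$unit_label, label = name)
  list(series = series, model = tp$model, template = name)
}
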