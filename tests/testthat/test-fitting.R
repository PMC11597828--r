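test_that("noiseless single-stage profile is recovered to high accuracy", {
  truth <- pbftpk_model(absorption_schedule(0.75, 0.031), one_compartment(0.64))
  ts <- c(0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 5, 6, 8, 10)
  ser <- conc_series(ts, concentration(truth, ts))
  fit <- fit_pbftpk(ser, "one_compartment", n_stages = 1, seed = 1)
  expect_true(fit$converged)
  expect_equal(fit$estimates[["tau1"]], 0.75, tolerance = 0.005)
  expect_equal(fit$estimates[["r1"]], 0.031, tolerance = 0.005)
  expect_equal(fit$estimates[["kel"]], 0.64, tolerance = 0.005)
  expect_lt(fit$ssr, 1e-12 * max(ser$concentrations)^2)
  # uncertainty machinery delivers a coherent result
  expect_true(all(is.finite(fit$standard_errors)))
  expect_equal(dim(fit$covariance), c(3L, 3L))
  expect_equal(fit$correlation[1, 1], 1)
  expect_equal(fit$covariance, t(fit$covariance))
  expect_equal(length(fit$residuals), fit$n_obs)
})

test_that("degenerate inputs are rejected with informative messages", {
  ser0 <- conc_series(0:9, rep(0, 10))
  expect_error(fit_pbftpk(ser0, "one_compartment", 1), "no signal")
  short <- conc_series(c(0, 1, 2), c(0, 1, 0.5))
  expect_error(fit_pbftpk(short, "one_compartment", 1), "at least 5")
  expect_error(fit_bateman(conc_series(1, 1)), "at least 5")
  # no data beyond the initial-guess absorption window
  early <- conc_series(c(0.1, 0.2, 0.3, 0.4, 0.5), c(1, 2, 3, 4, 5))
  expect_error(fit_pbftpk(early, "one_compartment", 1,
                          initial_guess = c(tau1 = 10)),
               "after the initial-guess")
})

test_that("noiseless three-stage profile recovers every duration within 1%", {
  fx <- study_fixture("theodur_like", noise_model())
  fit <- fit_pbftpk(fx$series, "one_compartment", n_stages = 3, seed = 1)
  truth <- fx$model$schedule$stages$duration
  for (i in 1:3)
    expect_equal(fit$estimates[[paste0("tau", i)]], truth[i],
                 tolerance = 0.01)
  expect_equal(fit$model$schedule$total_duration, 11.6, tolerance = 0.01)
})

test_that("noiseless randomized round trips recover parameters within 1%", {
  set.seed(202)
  scenarios <- expand.grid(n_stages = 1:3, two_cpt = c(FALSE, TRUE))
  for (row in seq_len(nrow(scenarios))) {
    for (rep in 1:3) {
      n <- scenarios$n_stages[row]
      model <- random_recovery_model(two_cpt = scenarios$two_cpt[row],
                                     n_stages = n)
      # dense sampling during absorption, sparser during elimination,
      # as clinical designs do; without early points tau and rate are
      # only jointly identified
      tau <- model$schedule$total_duration
      horizon <- tau + 4 / slowest_rate(model)
      ts <- sort(unique(c(seq(tau / 10, tau, length.out = 10),
                          seq(tau, horizon, length.out = 30)[-1])))
      ser <- conc_series(ts, concentration(model, ts))
      type <- if (scenarios$two_cpt[row]) "two_compartment" else "one_compartment"
      fit <- fit_pbftpk(ser, type, n_stages = n, seed = rep)
      expect_lt(fit$ssr, 1e-12 * max(ser$concentrations)^2)
      truth <- c(model$schedule$stages$duration, model$schedule$stages$rate,
                 if (scenarios$two_cpt[row])
                   with(model$disposition, c(k12, k21, k10))
                 else model$disposition$kel)
      expect_equal(unname(fit$estimates), truth, tolerance = 0.01)
    }
  }
})

test_that("identical seeds give identical fits, different seeds may differ", {
  fx <- study_fixture("theotrim_like", noise_model(0.05, seed = 11))
  f1 <- fit_pbftpk(fx$series, "one_compartment", 2, seed = 42)
  f2 <- fit_pbftpk(fx$series, "one_compartment", 2, seed = 42)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$ssr, f2$ssr)
  expect_identical(f1$covariance, f2$covariance)
})

test_that("multistart fitting does not disturb the caller's RNG stream", {
  fx <- study_fixture("ketoprofen_like", noise_model())
  set.seed(5)
  a <- runif(1)
  set.seed(5)
  invisible(fit_pbftpk(fx$series, "one_compartment", 1, seed = 9))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("Bateman round trip recovers parameters; PBFTPK data defeat it", {
  truth <- bateman_model(ka = 1.4, kel = 0.25, scale = 0.9)
  ts <- c(0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 10, 12, 16)
  ser <- conc_series(ts, concentration(truth, ts))
  fit <- fit_bateman(ser, seed = 1)
  expect_true(fit$converged)
  expect_equal(fit$estimates[["ka"]], 1.4, tolerance = 0.005)
  expect_equal(fit$estimates[["kel"]], 0.25, tolerance = 0.005)
  expect_equal(fit$estimates[["scale"]], 0.9, tolerance = 0.005)

  # on three-stage finite-absorption data the Bateman fit is inferior
  fx <- study_fixture("theodur_like", noise_model())
  fb <- fit_bateman(fx$series, seed = 1)
  f3 <- fit_pbftpk(fx$series, "one_compartment", 3, seed = 1)
  expect_gt(fb$ssr, f3$ssr)
})

test_that("model comparison ranks the generating model first", {
  fx <- study_fixture("theotrim_like", noise_model())
  cands <- lapply(1:3, function(k)
    list(disposition_type = "one_compartment", n_stages = k))
  cmp <- compare_models(fx$series, cands, seed = 1)
  expect_equal(cmp$table$label[cmp$ranking[1]], "one_compartment/2-stage")
  expect_true(all(diff(cmp$table$aicc[cmp$ranking]) >= 0))

  # single candidate: ranking of length one
  cmp1 <- compare_models(fx$series, cands[2], seed = 1)
  expect_length(cmp1$ranking, 1L)

  # Bateman against the 3-stage model on Theodur-like data
  fx3 <- study_fixture("theodur_like", noise_model())
  cmp2 <- compare_models(fx3$series, list(
    "bateman", list(disposition_type = "one_compartment", n_stages = 3)),
    seed = 1)
  expect_equal(cmp2$table$label[cmp2$ranking[1]], "one_compartment/3-stage")

  # a failing candidate is recorded, not dropped
  tiny <- conc_series(c(0.5, 1, 2, 3, 4, 6, 8, 10),
                      concentration(fx$model, c(0.5, 1, 2, 3, 4, 6, 8, 10)))
  cmp3 <- compare_models(tiny, list(
    list(disposition_type = "two_compartment", n_stages = 3),
    list(disposition_type = "one_compartment", n_stages = 2)), seed = 1)
  expect_match(cmp3$table$status[1], "failed")
  expect_equal(nrow(cmp3$table), 2L)
})

test_that("reported standard errors track Monte-Carlo spread within a factor of 2", {
  tau_hat <- se_hat <- numeric(200)
  for (i in seq_len(200)) {
    fx <- study_fixture("ketoprofen_like",
                        noise_model(proportional_cv = 0.05, seed = 300 + i))
    fit <- fit_pbftpk(fx$series, "one_compartment", 1, seed = i)
    tau_hat[i] <- fit$estimates[["tau1"]]
    se_hat[i] <- fit$standard_errors[["tau1"]]
  }
  ratio <- median(se_hat) / sd(tau_hat)
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})
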