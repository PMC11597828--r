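test_that("domain type constructors enforce their invariants", {
  expect_error(conc_series(c(0, 1, 1), c(0, 1, 2)), "strictly increasing")
  expect_error(conc_series(c(0, 1), c(0, -1)), ">= 0")
  expect_error(conc_series(c(-1, 1), c(0, 1)), "first time")
  expect_error(conc_series(c(0, 1), c(0, 1, 2)), "lengths differ")
  expect_error(absorption_schedule(c(1, -1), c(1, 1)), "> 0")
  expect_error(absorption_schedule(numeric(0), numeric(0)), "at least one stage")
  expect_error(one_compartment(0), "> 0")
  expect_error(two_compartment(0.5, -0.1, 0.2), "> 0")
  expect_error(bateman_model(1, 1, 1), "ka == kel")

  sch <- absorption_schedule(c(2.1, 5.3), c(1.16, 0.80))
  expect_equal(sch$total_duration, 7.4)
  expect_equal(sch$breakpoints, c(2.1, 7.4))
  expect_equal(sch$stages$amount, c(2.1 * 1.16, 5.3 * 0.80))

  d <- two_compartment(0.6, 0.4, 0.1)
  expect_gt(d$alpha, d$beta)
  expect_gt(d$beta, 0)
  # hybrid constants satisfy sum and product identities
  expect_equal(d$alpha + d$beta, 0.6 + 0.4 + 0.1)
  expect_equal(d$alpha * d$beta, 0.4 * 0.1)
})

test_that("one-compartment closed form matches frozen values and the ODE oracle", {
  sch <- absorption_schedule(1, 1)
  disp <- one_compartment(1)
  # frozen values from numerical integration of dC/dt = r 1{t<tau} - kel C
  expect_equal(concentration_one_compartment(sch, disp, 1), 0.63212,
               tolerance = 1e-4)
  expect_equal(concentration_one_compartment(sch, disp, 2), 0.23254,
               tolerance = 1e-4)
  expect_identical(concentration_one_compartment(sch, disp, 0), 0)
  expect_error(concentration_one_compartment(sch, disp, -0.5), "negative")

  model <- pbftpk_model(sch, disp)
  expect_equal(concentration(model, c(1, 2)), ode_oracle(model, c(1, 2)),
               tolerance = 1e-8)

  # post-absorption decay is a pure exponential from C(tau)
  t_after <- c(1.5, 3, 6)
  expect_equal(concentration(model, t_after),
               concentration(model, 1) * exp(-(t_after - 1)),
               tolerance = 1e-12)
})

test_that("two-compartment closed form matches the ODE oracle and decouples as k12 -> 0", {
  sch <- absorption_schedule(2, 1)
  model <- pbftpk_model(sch, two_compartment(0.5, 0.3, 0.2))
  expect_identical(concentration(model, 0), 0)
  expect_error(concentration(model, -1), "negative")
  ts <- c(0.5, 1, 2, 3, 5, 10)
  expect_equal(concentration(model, ts), ode_oracle(model, ts),
               tolerance = 1e-8)

  # with negligible central->peripheral transfer the central compartment
  # behaves as a one-compartment model with kel = k10
  near_one <- pbftpk_model(sch, two_compartment(1e-10, 0.3, 0.2))
  one <- concentration_one_compartment(sch, one_compartment(0.2), ts)
  expect_equal(concentration(near_one, ts), one, tolerance = 1e-9)
})

test_that("closed forms agree with the ODE oracle over randomized models", {
  set.seed(101)
  for (rep in 1:12) {
    model <- random_model(two_cpt = rep %% 2 == 0)
    horizon <- 3 * model$schedule$total_duration + 5 / slowest_rate(model)
    ts <- seq(horizon / 50, horizon, length.out = 50)
    closed <- concentration(model, ts)
    ode <- ode_oracle(model, ts)
    expect_equal(closed, ode, tolerance = 1e-6)
  }
})

test_that("concentration is continuous across stage breakpoints", {
  set.seed(7)
  for (rep in 1:5) {
    model <- random_model(two_cpt = rep > 3, n_stages = 3)
    eps <- 1e-9
    for (b in model$schedule$breakpoints) {
      gap <- abs(concentration(model, b + eps) - concentration(model, b - eps))
      expect_lt(gap, 1e-6)
    }
  }
})

test_that("two equal-rate stages superpose to one combined stage", {
  two <- pbftpk_model(absorption_schedule(c(1.5, 2.5), c(0.4, 0.4)),
                      one_compartment(0.3))
  one <- pbftpk_model(absorption_schedule(4, 0.4), one_compartment(0.3))
  ts <- seq(0, 12, by = 0.25)
  expect_equal(concentration(two, ts), concentration(one, ts),
               tolerance = 1e-12)
})

test_that("Bateman curve has the analytic peak and matches direct evaluation", {
  m <- bateman_model(ka = 2, kel = 0.5, scale = 1)
  expect_identical(bateman_concentration(m, 0), 0)
  expect_error(bateman_concentration(m, -1), "negative")
  tmax <- log(2 / 0.5) / (2 - 0.5)
  expect_equal(tmax, 0.92420, tolerance = 1e-4)
  # grid search confirms the stationary point
  grid <- seq(0.01, 10, by = 1e-3)
  expect_equal(grid[which.max(bateman_concentration(m, grid))], tmax,
               tolerance = 1e-2)
  expect_equal(bateman_concentration(m, tmax),
               1 * 2 / (2 - 0.5) * (exp(-0.5 * tmax) - exp(-2 * tmax)))
  # single interior maximum: rises then falls
  C <- bateman_concentration(m, grid)
  expect_equal(sum(diff(sign(diff(C))) != 0), 1)
})

test_that("analytic AUC matches mass balance and numerical quadrature", {
  expect_equal(auc_infinity_analytic(
    pbftpk_model(absorption_schedule(1, 1), one_compartment(1))), 1.0)

  theodur <- pbftpk_model(
    absorption_schedule(c(4.2, 3.2, 4.2), c(0.0009, 0.0024, 0.0016)),
    one_compartment(0.1))
  expect_equal(auc_infinity_analytic(theodur), 0.1818, tolerance = 1e-3)
  expect_equal(numeric_auc(theodur, 200), auc_infinity_analytic(theodur),
               tolerance = 1e-3)

  two <- pbftpk_model(absorption_schedule(2, 0.5),
                      two_compartment(0.3, 0.4, 0.5))
  expect_equal(auc_infinity_analytic(two), 2.0)
  expect_equal(numeric_auc(two, 400, dt = 0.005), 2.0, tolerance = 1e-3)
})

test_that("cmax_tmax locates the peak", {
  m1 <- pbftpk_model(absorption_schedule(1, 1), one_compartment(1))
  expect_identical(cmax_tmax(m1)[["tmax"]], 1)

  # a second stage with zero rate cannot move the peak
  m2 <- pbftpk_model(absorption_schedule(c(1, 2), c(1, 0)), one_compartment(1))
  expect_identical(cmax_tmax(m2)[["tmax"]], 1)
  grid <- seq(0, 10, by = 1e-3)
  expect_equal(grid[which.max(concentration(m2, grid))], 1, tolerance = 2e-3)

  m3 <- pbftpk_model(absorption_schedule(2, 1), two_compartment(0.5, 0.3, 0.2))
  peak <- cmax_tmax(m3)
  expect_equal(peak[["tmax"]], grid[which.max(concentration(m3, grid))],
               tolerance = 1e-2)
  expect_equal(peak[["cmax"]], max(concentration(m3, grid)), tolerance = 1e-6)
})
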