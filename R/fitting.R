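#' Fit a PBFTPK model to a concentration-time series
#'
#' Ordinary (unweighted) least-squares estimation of a finite-absorption-
#' time model with `n_stages` successive zero-order input stages and one-
#' or two-compartment disposition, via Levenberg-Marquardt minimization
#' ([minpack.lm::nls.lm()]) on log-transformed parameters. The log
#' transform keeps every duration, rate and rate constant positive and
#' the stage breakpoints ordered without explicit constraints.
#'
#' Initialization: the elimination (or slow hybrid) rate constant comes
#' from a log-linear regression on the last third of the positive
#' observations; stage breakpoints split `[0, 1.2 * tmax_obs]` evenly;
#' rates start at the crude rising-limb slope `cmax_obs / tmax_obs`.
#' A multistart scheme runs the base start plus seeded log-normally
#' jittered restarts and keeps the best sum of squared residuals, ties
#' going to the first found; identical seeds give identical results.
#'
#' Standard errors derive from the Jacobian-based covariance at the
#' optimum, `cov = s2 * (J'J)^{-1}` with `s2 = SSR/(n_obs - n_params)`,
#' with the Jacobian evaluated numerically on the natural parameter scale.
#'
#' @param series A [conc_series()].
#' @param disposition_type `"one_compartment"` or `"two_compartment"`.
#' @param n_stages Number of input stages (1 to 3 supported).
#' @param initial_guess Optional named numeric vector overriding the
#'   automatic start (names among `tau1..tauN`, `r1..rN`, and `kel` or
#'   `k12`/`k21`/`k10`).
#' @param seed Integer seed driving the multistart jitter.
#' @param n_starts Minimum number of multistart runs (the first is
#'   unjittered); at least `2 * n_params + 4` runs are always used so the
#'   budget grows with model complexity.
#' @param loq Observations with concentration strictly below this limit of
#'   quantification are excluded from fitting (never imputed). Default 0
#'   excludes nothing.
#'
#' @return A `pbftpk_fit` object: `model_spec`, `estimates`,
#'   `standard_errors`, `covariance`, `correlation`, `residuals`,
#'   `fitted`, `ssr`, `converged`, `n_obs`, `n_params`, and `model`
#'   (the fitted [pbftpk_model()]).
#' @examples
#' truth <- pbftpk_model(absorption_schedule(0.75, 0.031), one_compartment(0.64))
#' ts <- seq(0, 8, by = 0.5)[-1]
#' ser <- conc_series(ts, concentration(truth, ts))
#' fit <- fit_pbftpk(ser, "one_compartment", n_stages = 1, seed = 1)
#' fit$estimates
#' @export
fit_pbftpk <- function(series, disposition_type = c("one_compartment",
                                                    "two_compartment"),
                       n_stages = 1L, initial_guess = NULL, seed = 1L,
                       n_starts = 10L, loq = 0) {
  stopifnot(inherits(series, "conc_series"))
  disposition_type <- match.arg(disposition_type)
  n_stages <- as.integer(n_stages)
  if (n_stages < 1L || n_stages > 3L)
    stop_pbftpk("'n_stages' must be 1, 2 or 3")
  ser <- apply_loq(series, loq)
  n_params <- if (disposition_type == "one_compartment")
    2L * n_stages + 1L else 2L * n_stages + 3L
  spec <- list(type = disposition_type, n_stages = n_stages)
  fit_ls(ser, spec, n_params, initial_guess, seed, n_starts,
         extra_starts = cascade_starts(ser, disposition_type, n_stages,
                                       seed))
}

# Starts for an n-stage fit derived from the (n-1)-stage optimum with one
# stage split in half; informed starts of this kind reach narrow global
# basins that breakpoint-grid jitter misses.
cascade_starts <- function(series, disposition_type, n_stages, seed) {
  if (n_stages < 2L) return(list())
  sub <- tryCatch(
    fit_pbftpk(series, disposition_type, n_stages - 1L, seed = seed,
               n_starts = 6L),
    error = function(e) NULL)
  if (is.null(sub)) return(list())
  e <- sub$estimates
  m <- n_stages - 1L
  taus <- unname(e[paste0("tau", seq_len(m))])
  rs <- unname(e[paste0("r", seq_len(m))])
  disp <- if (disposition_type == "one_compartment") e["kel"]
          else e[c("k12", "k21", "k10")]
  lapply(seq_len(m), function(i) {
    newt <- append(taus, taus[i] / 2, after = i)
    newt[i] <- newt[i] / 2
    newr <- append(rs, rs[i], after = i)
    c(setNames(newt, paste0("tau", seq_len(n_stages))),
      setNames(pmax(newr, 1e-12), paste0("r", seq_len(n_stages))),
      disp)
  })
}

#' Fit the Bateman comparator to a concentration-time series
#'
#' Least-squares fit of the first-order absorption/elimination curve with
#' parameters `ka`, `kel` and `scale`, using the same multistart
#' Levenberg-Marquardt and uncertainty machinery as [fit_pbftpk()].
#'
#' @inheritParams fit_pbftpk
#' @return A `pbftpk_fit` object with `model_spec$type = "bateman"` and a
#'   fitted [bateman_model()] in `$model`.
#' @examples
#' truth <- bateman_model(1.4, 0.25, 0.9)
#' ts <- c(0.5, 1, 1.5, 2, 3, 4, 6, 8, 12)
#' fit <- fit_bateman(conc_series(ts, concentration(truth, ts)), seed = 1)
#' fit$estimates
#' @export
fit_bateman <- function(series, initial_guess = NULL, seed = 1L,
                        n_starts = 10L, loq = 0) {
  stopifnot(inherits(series, "conc_series"))
  ser <- apply_loq(series, loq)
  if (length(ser$times) < 5L)
    stop_pbftpk(sprintf("Bateman fit requires at least 5 observations, got %d",
                        length(ser$times)))
  fit_ls(ser, list(type = "bateman", n_stages = NA_integer_), 3L,
         initial_guess, seed, n_starts, extra_starts = list())
}

apply_loq <- function(series, loq) {
  if (loq <= 0) return(series)
  keep <- series$concentrations >= loq
  if (!any(keep)) stop_pbftpk("no observations at or above the LOQ")
  conc_series(series$times[keep], series$concentrations[keep],
              series$unit_label, series$label)
}

# -- internal least-squares engine ------------------------------------------

param_names <- function(spec) {
  if (spec$type == "bateman") return(c("ka", "kel", "scale"))
  n <- spec$n_stages
  disp <- if (spec$type == "one_compartment") "kel" else c("k12", "k21", "k10")
  c(paste0("tau", seq_len(n)), paste0("r", seq_len(n)), disp)
}

build_model <- function(spec, p) {
  if (spec$type == "bateman")
    return(bateman_model(p[["ka"]], p[["kel"]], p[["scale"]]))
  n <- spec$n_stages
  sch <- absorption_schedule(p[paste0("tau", seq_len(n))],
                             p[paste0("r", seq_len(n))])
  disp <- if (spec$type == "one_compartment") one_compartment(p[["kel"]])
          else two_compartment(p[["k12"]], p[["k21"]], p[["k10"]])
  pbftpk_model(sch, disp)
}

predict_spec <- function(spec, p, t) {
  if (spec$type == "bateman") {
    # direct evaluation tolerating ka ~ kel during the search
    ka <- p[["ka"]]; kel <- p[["kel"]]; sc <- p[["scale"]]
    if (abs(ka - kel) < 1e-12 * max(ka, kel))
      return(sc * ka * t * exp(-ka * t))
    return(sc * ka / (ka - kel) * (exp(-kel * t) - exp(-ka * t)))
  }
  n <- spec$n_stages
  tau <- p[paste0("tau", seq_len(n))]
  r <- p[paste0("r", seq_len(n))]
  bp <- cumsum(tau)
  starts <- c(0, head(bp, -1L))
  C <- numeric(length(t))
  if (spec$type == "one_compartment") {
    kel <- p[["kel"]]
    ramp <- function(x) ifelse(x > 0, 1 - exp(-kel * x), 0)
    for (i in seq_len(n))
      C <- C + r[i] / kel * (ramp(t - starts[i]) - ramp(t - bp[i]))
  } else {
    s <- p[["k12"]] + p[["k21"]] + p[["k10"]]
    disc <- sqrt(max(s^2 - 4 * p[["k21"]] * p[["k10"]], 1e-300))
    a <- (s + disc) / 2; b <- (s - disc) / 2
    A <- (a - p[["k21"]]) / (a - b); B <- (p[["k21"]] - b) / (a - b)
    stepr <- function(x) ifelse(x > 0,
                                A * (1 - exp(-a * x)) / a +
                                B * (1 - exp(-b * x)) / b, 0)
    for (i in seq_len(n))
      C <- C + r[i] * (stepr(t - starts[i]) - stepr(t - bp[i]))
  }
  C
}

initial_params <- function(series, spec) {
  t <- series$times
  y <- series$concentrations
  pos <- which(y > 0)
  # terminal slope from the last third of positive observations
  k0 <- NA_real_
  if (length(pos) >= 3L) {
    idx <- tail(pos, max(3L, ceiling(length(pos) / 3)))
    sl <- coef(lm(log(y[idx]) ~ t[idx]))[2L]
    if (is.finite(sl) && sl < 0) k0 <- -sl
  }
  if (!is.finite(k0)) k0 <- 2 / max(t)
  imax <- which.max(y)
  tmax <- max(t[imax], t[t > 0][1L])
  cmax <- max(y)
  if (cmax <= 0) stop_pbftpk("series has no signal (all concentrations zero)")
  if (spec$type == "bateman") {
    ka0 <- max(3 / tmax, 2.5 * k0)
    return(c(ka = ka0, kel = k0, scale = cmax * 1.5))
  }
  n <- spec$n_stages
  tau0 <- rep(1.2 * tmax / n, n)
  r0 <- rep(cmax / tmax, n)
  p <- c(tau0, r0)
  names(p) <- c(paste0("tau", seq_len(n)), paste0("r", seq_len(n)))
  if (spec$type == "one_compartment") {
    p <- c(p, kel = unname(k0))
  } else {
    # chosen so the slow hybrid constant equals the terminal slope k0
    p <- c(p, k12 = unname(k0), k21 = 2 * unname(k0), k10 = 2 * unname(k0))
  }
  p
}

fit_ls <- function(series, spec, n_params, initial_guess, seed, n_starts,
                   extra_starts = list()) {
  t <- series$times
  y <- series$concentrations
  n_obs <- length(t)
  if (all(y == 0)) stop_pbftpk("series has no signal (all concentrations zero)")
  if (n_obs < n_params + 2L)
    stop_pbftpk(sprintf("need at least %d observations to fit %d parameters, got %d",
                        n_params + 2L, n_params, n_obs))
  pn <- param_names(spec)
  p0 <- initial_params(series, spec)
  if (!is.null(initial_guess)) {
    bad <- setdiff(names(initial_guess), pn)
    if (length(bad))
      stop_pbftpk("unknown parameters in initial_guess: ",
                  paste(bad, collapse = ", "))
    p0[names(initial_guess)] <- initial_guess
  }
  if (spec$type != "bateman") {
    tau_tot0 <- sum(p0[startsWith(names(p0), "tau")])
    if (!any(t > tau_tot0))
      stop_pbftpk("no observation lies after the initial-guess total duration; ",
                  "extend sampling or supply a smaller initial_guess")
  }
  theta0 <- log(p0)
  resid_fn <- function(theta) {
    p <- setNames(exp(pmin(pmax(theta, -30), 30)), pn)
    r <- y - predict_spec(spec, p, t)
    r[!is.finite(r)] <- 1e6
    r
  }
  # the start count grows with model complexity; starts combine coarse
  # rescalings of the guessed absorption duration (the main source of
  # multimodality) with jitter amplitudes cycling from local to global
  tau_idx <- which(startsWith(pn, "tau"))
  scales <- if (length(tau_idx)) c(1, 0.6, 1.5, 2.2) else 1
  n_starts_eff <- max(n_starts, 2L * n_params + 4L, 3L * length(scales))
  sds <- c(0, 0.15, 0.3, 0.5, 0.8)
  jitters <- with_seed(seed, {
    lapply(seq_len(n_starts_eff), function(j) {
      sc <- scales[1L + (j - 1L) %% length(scales)]
      sd <- sds[1L + ((j - 1L) %/% length(scales)) %% length(sds)]
      th <- rep(0, n_params)
      th[tau_idx] <- log(sc)
      if (sd > 0) th <- th + rnorm(n_params, 0, sd)
      th
    })
  })
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-13, ptol = 1e-11,
                                     maxiter = 400L)
  start_thetas <- c(lapply(jitters, function(jt) theta0 + jt),
                    lapply(extra_starts, function(p) log(unname(p[pn]))))
  best <- NULL
  for (th in start_thetas) {
    if (any(!is.finite(th))) next
    res <- tryCatch(minpack.lm::nls.lm(par = th, fn = resid_fn,
                                       control = ctrl),
                    error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$deviance < best$deviance - 1e-14 * best$deviance)
      best <- res
  }
  if (is.null(best))
    stop_pbftpk("all optimizer starts failed")
  # polish the winner from its own optimum
  polish <- tryCatch(minpack.lm::nls.lm(par = best$par, fn = resid_fn,
                                        control = ctrl),
                     error = function(e) NULL)
  if (!is.null(polish) && polish$deviance <= best$deviance) best <- polish
  p_hat <- setNames(exp(pmin(pmax(best$par, -30), 30)), pn)
  fitted <- predict_spec(spec, p_hat, t)
  residuals <- y - fitted
  ssr <- sum(residuals^2)
  converged <- best$info %in% 1:3 || ssr <= 1e-20 * max(y)^2
  unc <- fit_uncertainty(spec, p_hat, t, ssr, n_obs, n_params)
  structure(
    list(model_spec = spec,
         estimates = p_hat,
         standard_errors = unc$se,
         covariance = unc$cov,
         correlation = unc$cor,
         residuals = residuals,
         fitted = fitted,
         ssr = ssr,
         converged = converged,
         optimizer_info = best$info,
         optimizer_message = best$message,
         n_obs = n_obs,
         n_params = n_params,
         series_label = series$label,
         model = build_model(spec, p_hat)),
    class = "pbftpk_fit")
}

fit_uncertainty <- function(spec, p_hat, t, ssr, n_obs, n_params) {
  J <- matrix(NA_real_, n_obs, n_params, dimnames = list(NULL, names(p_hat)))
  for (k in seq_len(n_params)) {
    h <- max(1e-6 * abs(p_hat[k]), 1e-10)
    pp <- p_hat; pp[k] <- pp[k] + h
    pm <- p_hat; pm[k] <- max(pm[k] - h, 1e-300)
    J[, k] <- (predict_spec(spec, pp, t) - predict_spec(spec, pm, t)) /
      (pp[k] - pm[k])
  }
  s2 <- ssr / max(n_obs - n_params, 1L)
  JtJ <- crossprod(J)
  inv <- tryCatch(solve(JtJ), error = function(e) {
    sv <- svd(JtJ)
    keep <- sv$d > max(sv$d) * 1e-12
    sv$v[, keep, drop = FALSE] %*%
      (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
  })
  cov <- s2 * (inv + t(inv)) / 2
  dimnames(cov) <- list(names(p_hat), names(p_hat))
  se <- sqrt(pmax(diag(cov), 0))
  cr <- cov / outer(se, se)
  cr[!is.finite(cr)] <- NA_real_
  diag(cr) <- 1
  list(se = se, cov = cov, cor = cr)
}

#' @export
print.pbftpk_fit <- function(x, ...) {
  lbl <- if (x$model_spec$type == "bateman") "Bateman"
         else sprintf("%d-stage %s PBFTPK", x$model_spec$n_stages,
                      sub("_", "-", x$model_spec$type))
  cat(sprintf("<pbftpk_fit> %s model, %d obs, SSR = %.4g, %s\n",
              lbl, x$n_obs, x$ssr,
              if (x$converged) "converged" else "NOT converged"))
  est <- data.frame(estimate = x$estimates, se = x$standard_errors)
  print(signif(est, 4))
  invisible(x)
}

#' Fit and rank candidate models on one series
#'
#' Fits every candidate (stage counts for a disposition, and/or the
#' Bateman comparator) and ranks them by a small-sample-corrected
#' information criterion computed from the Gaussian SSR,
#' `AICc = n log(SSR/n) + 2k + 2k(k+1)/(n-k-1)` with `k = n_params + 1`
#' (the residual variance counts as a parameter). The SSR entering the
#' criterion is floored at `(1e-9 * Cmax)^2` per point, so fits that are
#' exact to numerical precision (noiseless data) are separated by
#' parsimony alone; explicit ties also go to the model with fewer
#' parameters. Candidates that fail to fit are recorded as failed, never
#' silently dropped.
#'
#' @param series A [conc_series()].
#' @param candidates List of candidate specs; each element is either the
#'   string `"bateman"` or a list with `disposition_type` and `n_stages`.
#' @param seed Integer seed forwarded to every fit.
#' @return A `model_comparison` object with `$table` (label, n_params,
#'   ssr, aicc, converged, status), `$ranking` (row indices, best first),
#'   and `$fits` (the underlying `pbftpk_fit` objects).
#' @examples
#' truth <- pbftpk_model(absorption_schedule(c(1.2, 1.3), c(0.0068, 0.0011)),
#'                       one_compartment(0.12))
#' ts <- c(0.25, 0.5, 1, 1.5, 2, 2.5, 3, 4, 6, 8, 12, 16, 24)
#' ser <- conc_series(ts, concentration(truth, ts))
#' cmp <- compare_models(ser, list(
#'   list(disposition_type = "one_compartment", n_stages = 1),
#'   list(disposition_type = "one_compartment", n_stages = 2)), seed = 1)
#' cmp$table$label[cmp$ranking[1]]
#' @export
compare_models <- function(series, candidates, seed = 1L) {
  stopifnot(inherits(series, "conc_series"), length(candidates) >= 1L)
  fits <- vector("list", length(candidates))
  rows <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    cand <- candidates[[i]]
    fit <- tryCatch({
      if (identical(cand, "bateman"))
        fit_bateman(series, seed = seed)
      else
        fit_pbftpk(series, disposition_type = cand$disposition_type,
                   n_stages = cand$n_stages, seed = seed)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      lbl <- if (identical(cand, "bateman")) "bateman"
             else sprintf("%s/%d-stage", cand$disposition_type, cand$n_stages)
      rows[[i]] <- data.frame(label = lbl, n_params = NA_integer_,
                              ssr = NA_real_, aicc = NA_real_,
                              converged = FALSE,
                              status = paste("failed:", conditionMessage(fit)))
      next
    }
    fits[[i]] <- fit
    lbl <- if (fit$model_spec$type == "bateman") "bateman"
           else sprintf("%s/%d-stage", fit$model_spec$type,
                        fit$model_spec$n_stages)
    floor_ssr <- fit$n_obs * (1e-9 * max(series$concentrations))^2
    rows[[i]] <- data.frame(label = lbl, n_params = fit$n_params,
                            ssr = fit$ssr,
                            aicc = aicc_from_ssr(max(fit$ssr, floor_ssr),
                                                 fit$n_obs, fit$n_params),
                            converged = fit$converged, status = "ok")
  }
  tab <- do.call(rbind, rows)
  ok <- which(!is.na(tab$aicc))
  ranking <- ok[order(tab$aicc[ok], tab$n_params[ok])]
  structure(list(table = tab, ranking = ranking, fits = fits),
            class = "model_comparison")
}

aicc_from_ssr <- function(ssr, n, n_params) {
  k <- n_params + 1L
  if (n - k - 1L <= 0L) return(Inf)
  n * log(max(ssr, 1e-300) / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>\n")
  tab <- x$table
  tab$rank <- NA_integer_
  tab$rank[x$ranking] <- seq_along(x$ranking)
  print(tab)
  invisible(x)
}
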