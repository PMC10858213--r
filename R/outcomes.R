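# Outcome statistics: ECM increase, functional-subunit survival, the
# fibrosis severity index, the dose-response fits and the FSU-level RBE.

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Increase in mean ECM concentration
#'
#' Mean ECM over all voxels of the simulation space minus the homeostatic
#' baseline mean, g/cm^3.
#'
#' @param world an `alveolar_world`.
#' @param baseline homeostatic grid-mean ECM concentration (record it from
#'   the prepared world before irradiation).
#' @return ECM increase, g/cm^3.
#' @export
delta_ecm <- function(world, baseline) {
  unname(grid_mean_concentration(world$grid)[["ECM"]]) - baseline
}

#' Functional-subunit survival
#'
#' An alveolus (the lung's functional subunit) survives while it still
#' contains at least one healthy AEC2; full depletion is absorbing.
#'
#' @param world an `alveolar_world`.
#' @return surviving fraction of the alveoli, in 0..1.
#' @export
fsu_survival <- function(world) {
  a <- world$agents
  healthy <- a$alv[a$type == 2L & a$state == 0L]
  length(intersect(world$alveoli$id, unique(healthy))) / nrow(world$alveoli)
}

#' Total segment volume
#'
#' Sum of the alveolar volumes (spherical shape assumed), cm^3.
#'
#' @param world_or_geometry an `alveolar_world` or `segment_geometry`.
#' @return volume, cm^3.
#' @export
segment_volume <- function(world_or_geometry) {
  alv <- world_or_geometry$alveoli
  sum((4 / 3) * pi * (alv$diameter / 2 * 1e-4)^3)  # um -> cm
}

#' Fibrosis severity index
#'
#' RSI = sqrt(dECM_late * dV), g^(1/2), combining the late ECM increase with
#' the functional-subunit volume term. By default `dV` is the *lost*
#' surviving volume, `V_total * (1 - SF)`, which makes the index zero for an
#' intact segment and monotone in damage (and matches the saturating
#' erf-shaped dose response used to fit it); `literal_volume = TRUE` uses
#' `V_total * SF` instead (the verbal reading "volume times the surviving
#' fraction").
#'
#' @param delta_ecm_late late ECM increase, g/cm^3 (negative values are
#'   clamped to 0).
#' @param surviving_fraction FSU surviving fraction in 0..1.
#' @param total_volume total segment volume, cm^3.
#' @param literal_volume see above.
#' @return RSI, g^(1/2).
#' @export
rsi <- function(delta_ecm_late, surviving_fraction, total_volume,
                literal_volume = FALSE) {
  if (any(surviving_fraction < 0 | surviving_fraction > 1))
    stop("surviving_fraction must be in [0, 1]")
  if (any(total_volume < 0)) stop("total_volume must be >= 0")
  dv <- if (literal_volume) total_volume * surviving_fraction
        else total_volume * (1 - surviving_fraction)
  sqrt(pmax(delta_ecm_late, 0) * dv)
}

#' First-order error propagation for the RSI
#'
#' Delta-method propagation of the ΔECM and FSU-survival standard errors
#' through the severity index.
#'
#' @param delta_ecm_late,surviving_fraction,total_volume point values as in
#'   [rsi()].
#' @param sem_delta_ecm,sem_sf standard errors of the mean of the two
#'   inputs.
#' @return SEM of the RSI, g^(1/2) (0 when the index itself is 0).
#' @export
propagate_rsi_sem <- function(delta_ecm_late, surviving_fraction,
                              total_volume, sem_delta_ecm, sem_sf) {
  r <- rsi(delta_ecm_late, surviving_fraction, total_volume)
  out <- numeric(length(r))
  pos <- r > 0
  dE <- total_volume * (1 - surviving_fraction) / (2 * r[pos])
  dS <- -delta_ecm_late[pos] * total_volume / (2 * r[pos])
  out[pos] <- sqrt((dE * sem_delta_ecm[pos])^2 + (dS * sem_sf[pos])^2)
  out
}

# ------------------------------------------------------------- fitting -----

new_fit_result <- function(model, parameters, covariance, rss, fn, data) {
  structure(list(model = model, parameters = parameters,
                 covariance = covariance, residual_norm = sqrt(rss),
                 fn = fn, data = data),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Dose-response fit [", x$model, "]\n", sep = "")
  print(signif(x$parameters, 5))
  cat("residual norm:", signif(x$residual_norm, 4), "\n")
  invisible(x)
}

#' @export
predict.fit_result <- function(object, dose, ...) object$fn(dose)

# Levenberg-Marquardt with a small multi-start grid; returns the best
# converged fit (half-saturation started at the dose quantiles, saturation
# at the max observed response).
multistart_fit <- function(formula, data, starts, lower, upper) {
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = st,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("dose-response fit did not converge from any start")
  best
}

#' Sigmoid fit of the ECM dose response
#'
#' Fits `dECM(D) = dECM_max / (1 + exp(4 * gamma * (1 - D / D50)))` to the
#' (dose, ΔECM) points: `dECM_max` is the saturation, `gamma` the steepness
#' and `D50` the dose at half saturation. Used for both the early and the
#' late ECM components.
#'
#' @param dose doses, Gy.
#' @param decm ΔECM values, g/cm^3.
#' @param weights optional fit weights (e.g. 1/SEM^2); unweighted by
#'   default.
#' @return a `fit_result` with parameters `decm_max`, `gamma`, `d50`.
#' @export
fit_ecm_sigmoid <- function(dose, decm, weights = NULL) {
  df <- data.frame(D = dose, y = decm,
                   w = if (is.null(weights)) 1 else weights)
  ymax <- max(df$y)
  qs <- stats::quantile(df$D[df$D > 0], c(0.25, 0.5, 0.75), names = FALSE)
  starts <- lapply(qs, function(q)
    list(ymax_ = ymax, gamma_ = 1, d50_ = q))
  best <- multistart_fit(
    y ~ ymax_ / (1 + exp(4 * gamma_ * (1 - D / d50_))), df, starts,
    lower = c(0, 1e-3, 1e-3), upper = c(Inf, 100, 1e4))
  cf <- stats::coef(best$fit)
  pars <- c(decm_max = unname(cf["ymax_"]), gamma = unname(cf["gamma_"]),
            d50 = unname(cf["d50_"]))
  fn <- function(D) pars[["decm_max"]] /
    (1 + exp(4 * pars[["gamma"]] * (1 - D / pars[["d50"]])))
  new_fit_result("ecm_sigmoid", pars, stats::vcov(best$fit), best$rss, fn, df)
}

#' Erf fit of the RSI dose response
#'
#' Fits `RSI(D) = A/2 * (1 - erf(sqrt(pi) * gamma * (1 - D / ED50)))`:
#' `A` is the saturation, `gamma` the steepness and `ED50` the dose at half
#' the maximum index. Monotone increasing in dose for gamma > 0.
#'
#' @param dose doses, Gy.
#' @param rsi_values RSI values, g^(1/2).
#' @param weights optional fit weights.
#' @return a `fit_result` with parameters `A`, `gamma`, `ed50`.
#' @export
fit_rsi_erf <- function(dose, rsi_values, weights = NULL) {
  df <- data.frame(D = dose, y = rsi_values,
                   w = if (is.null(weights)) 1 else weights)
  ymax <- max(df$y)
  qs <- stats::quantile(df$D[df$D > 0], c(0.25, 0.5, 0.75), names = FALSE)
  starts <- lapply(qs, function(q) list(A_ = ymax, gamma_ = 1, ed50_ = q))
  erf_ <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  best <- multistart_fit(
    y ~ 0.5 * A_ * (1 - erf_(sqrt(pi) * gamma_ * (1 - D / ed50_))),
    df, starts, lower = c(0, 1e-3, 1e-3), upper = c(Inf, 100, 1e4))
  cf <- stats::coef(best$fit)
  pars <- c(A = unname(cf["A_"]), gamma = unname(cf["gamma_"]),
            ed50 = unname(cf["ed50_"]))
  fn <- function(D) 0.5 * pars[["A"]] *
    (1 - erf(sqrt(pi) * pars[["gamma"]] * (1 - D / pars[["ed50"]])))
  new_fit_result("rsi_erf", pars, stats::vcov(best$fit), best$rss, fn, df)
}

#' Critical-volume fit of the FSU survival
#'
#' Fits the LQ-critical-volume survival
#' `P(D) = 1 - (1 - exp(-alpha D - beta D^2))^N` with `N` the homeostatic
#' number of AEC2 per alveolus (fixed, or free when `n_aec2 = NULL`).
#' `P(0) = 1` is structural. With `log_scale = TRUE` the squared error is
#' taken on log survival, emphasising the low-survival tail.
#'
#' @param dose doses, Gy.
#' @param survival FSU surviving fractions in 0..1.
#' @param n_aec2 fixed N (default NULL: fitted).
#' @param log_scale fit on log10 survival (points at 0 are floored to
#'   `1e-4`).
#' @return a `fit_result` with parameters `alpha`, `beta`, `n_aec2`.
#' @export
fit_fsu_survival <- function(dose, survival, n_aec2 = NULL,
                             log_scale = FALSE) {
  df <- data.frame(D = dose, y = survival)
  if (log_scale) df$y <- log10(pmax(df$y, 1e-4))
  model_fn <- function(D, a, b, N) 1 - (1 - exp(-a * D - b * D^2))^N
  starts <- list()
  for (a0 in c(0.05, 0.2, 0.5))
    starts[[length(starts) + 1]] <-
      if (is.null(n_aec2)) list(a_ = a0, b_ = a0 / 10, N_ = 50)
      else list(a_ = a0, b_ = a0 / 10)
  if (is.null(n_aec2)) {
    form <- if (log_scale)
      y ~ log10(pmax(1 - (1 - exp(-a_ * D - b_ * D^2))^N_, 1e-4))
    else y ~ 1 - (1 - exp(-a_ * D - b_ * D^2))^N_
    best <- multistart_fit(form, df, starts,
                           lower = c(0, 0, 1), upper = c(10, 10, 1e5))
    cf <- stats::coef(best$fit)
    pars <- c(alpha = unname(cf["a_"]), beta = unname(cf["b_"]),
              n_aec2 = unname(cf["N_"]))
  } else {
    df$N_ <- n_aec2
    form <- if (log_scale)
      y ~ log10(pmax(1 - (1 - exp(-a_ * D - b_ * D^2))^N_, 1e-4))
    else y ~ 1 - (1 - exp(-a_ * D - b_ * D^2))^N_
    best <- multistart_fit(form, df, starts,
                           lower = c(0, 0), upper = c(10, 10))
    cf <- stats::coef(best$fit)
    pars <- c(alpha = unname(cf["a_"]), beta = unname(cf["b_"]),
              n_aec2 = n_aec2)
  }
  fn <- function(D) model_fn(D, pars[["alpha"]], pars[["beta"]],
                             pars[["n_aec2"]])
  new_fit_result("fsu_critical_volume", pars, stats::vcov(best$fit),
                 best$rss, fn, df)
}

#' FSU-level relative biological effectiveness
#'
#' Ratio of the photon to the proton dose producing the same fitted FSU
#' survival: each fitted curve is inverted numerically at the isoeffect
#' level (bisection to 1e-6 Gy) and the dose ratio returned. The value
#' depends only on the two fitted curves, not on their parameterization.
#'
#' @param fit_photon,fit_proton `fit_result` objects from
#'   [fit_fsu_survival()] (any monotone-decreasing dose-response fit works).
#' @param level isoeffect survival level (e.g. 0.5, 0.37, 0.1).
#' @param dose_max upper bracket for the inversion, Gy.
#' @return RBE_FSU (dimensionless).
#' @export
rbe_fsu <- function(fit_photon, fit_proton, level, dose_max = 200) {
  invert <- function(fit) {
    f <- function(D) predict(fit, D) - level
    lo <- f(0); hi <- f(dose_max)
    if (lo * hi > 0)
      stop(sprintf("isoeffect level %g not attained on [0, %g] Gy",
                   level, dose_max))
    stats::uniroot(f, c(0, dose_max), tol = 1e-6)$root
  }
  invert(fit_photon) / invert(fit_proton)
}

#' Aggregate replicate outcomes into a dose-response table
#'
#' Means and standard errors of the mean over replicates for every
#' (dose, fractions) cell of a campaign's raw outcome rows.
#'
#' @param rows data.frame with columns `total_dose`, `fractions`,
#'   `replicate` and outcome columns (`delta_ecm_early`, `delta_ecm_late`,
#'   `fsu_survival`, `rsi`).
#' @return data.frame with one row per (total_dose, fractions): outcome
#'   means, their SEMs (NA when n < 2) and `n`.
#' @export
aggregate_dose_response <- function(rows) {
  key <- interaction(rows$total_dose, rows$fractions, drop = TRUE)
  out <- lapply(split(rows, key), function(g) {
    sem <- function(v) if (nrow(g) >= 2) stats::sd(v) / sqrt(nrow(g))
                       else NA_real_
    data.frame(
      total_dose = g$total_dose[1], fractions = g$fractions[1],
      n = nrow(g),
      delta_ecm_early = mean(g$delta_ecm_early),
      sem_delta_ecm_early = sem(g$delta_ecm_early),
      delta_ecm_late = mean(g$delta_ecm_late),
      sem_delta_ecm_late = sem(g$delta_ecm_late),
      fsu_survival = mean(g$fsu_survival),
      sem_fsu_survival = sem(g$fsu_survival),
      rsi = mean(g$rsi), sem_rsi = sem(g$rsi))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$fractions, out$total_dose), ]
  rownames(out) <- NULL
  out
}

#' Export a fit result as JSON
#'
#' @param fit a `fit_result`.
#' @param file path of the JSON file.
#' @return the path, invisibly.
#' @export
write_fit_json <- function(fit, file) {
  jsonlite::write_json(
    list(model = fit$model, parameters = as.list(fit$parameters),
         residual_norm = fit$residual_norm),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
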