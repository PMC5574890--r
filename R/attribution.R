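#' Counterfactual contribution of one driver to a response trend
#'
#' The temporal contribution of a driver is the difference between the trend
#' of the averaged model's predictions over the panel and the trend of the
#' predictions when that driver is held constant -- replaced, within each
#' site, by the site's median value -- while all other covariates follow the
#' observations. Both trends are evaluated with the same fixed mixed-model
#' covariance structure (random site intercepts and slopes, AR(1) residuals,
#' with variance parameters taken from the observed-response trend fit), so
#' that the decomposition across drivers is exact. Because the contribution
#' is a linear functional of the fitted coefficients (the site BLUPs cancel
#' between the factual and counterfactual predictions), its standard error
#' follows from the coefficient covariance by the delta method, combined
#' across retained models with the revised Burnham-Anderson unconditional
#' estimator. The P value is the two-sided normal probability.
#'
#' @param avg an [average_model()] result.
#' @param panel the panel the contributions refer to.
#' @param driver a temporal covariate of the model (e.g. `"CO2"`,
#'   `"Sdep_an"`, `"MAT_an"`, `"LAI_an"`).
#' @param struct fixed covariance structure for the trend functional; when
#'   `NULL` it is taken from a trend fit of the observed response.
#' @param include_random unused by the value (the site BLUPs cancel exactly
#'   between the factual and counterfactual predictions); kept so callers can
#'   treat [contribution()] and [decompose_trend()] uniformly.
#' @return An object of class `contribution_record`: `driver`,
#'   `contribution` (response units yr^-1), `contribution_se`, `p_value`,
#'   `in_model`.
#' @export
contribution <- function(avg, panel, driver, struct = NULL,
                         include_random = TRUE) {
  stopifnot(inherits(avg, "averaged_model"))
  check_columns(panel, c(avg$group, avg$time, driver), "panel")
  if (is.null(struct)) {
    obs <- mean_trend_lmm(panel, avg$response, group = avg$group,
                          time = avg$time)
    struct <- trend_structure(obs$fit)
  }
  if (!covariate_in_model(avg, driver)) {
    return(structure(list(driver = driver, contribution = 0,
                          contribution_se = 0, p_value = NA_real_,
                          in_model = FALSE),
                     class = "contribution_record"))
  }
  cf <- hold_constant(panel, driver, avg$group)
  g <- panel[[avg$group]]
  # the trend functional as an explicit weight vector: it has per-site fixed
  # intercepts, so site-constant shifts -- e.g. the site median a
  # held-constant driver is pinned to, or the site BLUPs common to both
  # predictions -- contribute exactly zero trend
  w <- gls_slope_weights(panel[[avg$time]], g, struct)
  # per retained model: contribution c_m = w' (X_full - X_cf) beta_m, a
  # linear functional of beta_m, with delta-method variance l' V_m l
  cs <- vs <- numeric(length(avg$fits))
  for (m in seq_along(avg$fits)) {
    f <- avg$fits[[m]]
    dX <- model_matrix_lmm(f, panel) - model_matrix_lmm(f, cf)
    cs[m] <- sum(w * as.numeric(dX %*% f$beta))
    l <- as.numeric(crossprod(dX, w))
    vs[m] <- as.numeric(t(l) %*% f$vcov %*% l)
  }
  con <- sum(avg$weights * cs)
  se <- sum(avg$weights * sqrt(vs + (cs - con)^2))
  structure(list(driver = driver, contribution = con, contribution_se = se,
                 p_value = if (se > 0) 2 * pnorm(-abs(con) / se)
                           else as.numeric(con == 0),
                 in_model = TRUE),
            class = "contribution_record")
}

hold_constant <- function(panel, driver, group) {
  med <- tapply(panel[[driver]], panel[[group]],
                function(x) median(x, na.rm = TRUE))
  panel[[driver]] <- as.numeric(med[as.character(panel[[group]])])
  panel
}

#' @export
print.contribution_record <- function(x, ...) {
  cat(sprintf("Contribution of %s: %.4g +/- %.4g (P = %.4g)%s\n",
              x$driver, x$contribution, x$contribution_se,
              x$p_value, if (x$in_model) "" else " [not in retained models]"))
  invisible(x)
}

#' Decompose an observed trend into per-driver contributions
#'
#' Computes the observed trend of the response (mixed model with site random
#' slopes and AR(1) residuals), the trend of the full averaged-model
#' predictions, the counterfactual contribution of each driver
#' (see [contribution()]), and the unknown remainder
#' `observed - sum(contributions)` with its propagated standard error. The
#' additivity identity `observed = sum(contributions) + unknown` holds to
#' machine precision by construction; on a noise-free linear panel with all
#' temporal covariates among `drivers`, the unknown term itself vanishes.
#'
#' @param avg an [average_model()] result.
#' @param panel the panel to decompose over (restrict years beforehand to
#'   choose the analysis period).
#' @param drivers character vector of temporal covariates.
#' @param include_random include site BLUPs in the predictions?
#' @return An object of class `attribution_result`: `observed_trend`,
#'   `observed_se`, `model_trend`, `model_se`, `contributions` (data.frame),
#'   `unknown`, `unknown_se`.
#' @export
decompose_trend <- function(avg, panel, drivers, include_random = TRUE) {
  stopifnot(inherits(avg, "averaged_model"))
  if (length(drivers) == 0) drivers <- character(0)
  obs_fit <- mean_trend_lmm(panel, avg$response, group = avg$group,
                            time = avg$time)
  struct <- trend_structure(obs_fit$fit)
  # observed trend evaluated with the same fixed structure (and the same
  # within-site centring as the contributions), so the decomposition
  # identity is exact rather than approximate
  g <- panel[[avg$group]]
  t_obs <- gls_trend(panel[[avg$time]], g,
                     center_by_site(panel[[avg$response]], g), struct)
  pred_full <- predict(avg, panel, include_random = include_random)
  t_model <- gls_trend(panel[[avg$time]], g,
                       center_by_site(pred_full, g), struct)

  recs <- lapply(drivers, function(d)
    contribution(avg, panel, d, struct = struct,
                 include_random = include_random))
  ctab <- data.frame(
    driver = vapply(recs, `[[`, character(1), "driver"),
    contribution = vapply(recs, `[[`, numeric(1), "contribution"),
    se = vapply(recs, `[[`, numeric(1), "contribution_se"),
    p_value = vapply(recs, `[[`, numeric(1), "p_value"),
    in_model = vapply(recs, `[[`, logical(1), "in_model"),
    stringsAsFactors = FALSE
  )
  unknown <- t_obs$slope - sum(ctab$contribution)
  unknown_se <- sqrt(t_obs$slope_se^2 + sum(ctab$se^2))
  structure(list(observed_trend = t_obs$slope, observed_se = t_obs$slope_se,
                 model_trend = t_model$slope, model_se = t_model$slope_se,
                 contributions = ctab,
                 unknown = unknown, unknown_se = unknown_se,
                 records = recs, structure = struct),
            class = "attribution_result")
}

#' @export
print.attribution_result <- function(x, ...) {
  cat(sprintf("Observed trend: %.4g +/- %.4g; model trend: %.4g +/- %.4g\n",
              x$observed_trend, x$observed_se, x$model_trend, x$model_se))
  print(x$contributions, digits = 4, row.names = FALSE)
  cat(sprintf("Unknown remainder: %.4g +/- %.4g\n", x$unknown, x$unknown_se))
  invisible(x)
}

#' Sensitivity of a response to a driver
#'
#' The temporal contribution divided by the driver's own trend: the change in
#' the response per unit change in the driver. The standard error follows
#' first-order (quotient-rule) propagation assuming independent errors,
#' `se = |s| sqrt((se_c/c)^2 + (se_t/t)^2)`; when the contribution is zero,
#' `se = se_c / |t|`. A one-sided P value for the sign of the sensitivity is
#' reported.
#'
#' @param contrib a [contribution()] record (or a list with `contribution`
#'   and `contribution_se`).
#' @param driver_trend a `trend_estimate` for the driver (slope must be
#'   nonzero).
#' @return An object of class `sensitivity_record`: `driver`, `sensitivity`,
#'   `sensitivity_se`, `driver_trend`, `driver_trend_se`, `p_value`.
#' @export
sensitivity <- function(contrib, driver_trend) {
  cval <- contrib$contribution
  cse <- contrib$contribution_se
  t <- driver_trend$slope
  tse <- driver_trend$slope_se
  if (t == 0) stop_fluxtrend("driver trend is zero: sensitivity undefined")
  if (cval == 0) {
    s <- 0
    se <- cse / abs(t)
  } else {
    s <- cval / t
    se <- abs(s) * sqrt((cse / cval)^2 + (tse / t)^2)
  }
  p <- if (se > 0) pnorm(-abs(s) / se) else if (s == 0) 0.5 else 0
  structure(list(driver = contrib$driver %||% NA_character_,
                 sensitivity = s, sensitivity_se = se,
                 driver_trend = t, driver_trend_se = tse, p_value = p),
            class = "sensitivity_record")
}

#' @export
print.sensitivity_record <- function(x, ...) {
  cat(sprintf("Sensitivity to %s: %.4g +/- %.4g per driver unit (one-sided P = %.4g)\n",
              x$driver, x$sensitivity, x$sensitivity_se, x$p_value))
  invisible(x)
}

#' Offset ratio between two contributions
#'
#' Expresses one driver's contribution as a percentage of another's, e.g. how
#' much a declining driver offsets the gain from an increasing one:
#' `100 |a/b|`, with quotient-rule standard error. The sign convention is
#' that `a` opposes `b`; the magnitude is reported.
#'
#' @param contrib_a,contrib_b contribution records (`contrib_b` nonzero).
#' @return A list with `percent` and `percent_se`.
#' @export
offset_ratio <- function(contrib_a, contrib_b) {
  a <- contrib_a$contribution; sa <- contrib_a$contribution_se
  b <- contrib_b$contribution; sb <- contrib_b$contribution_se
  if (b == 0) stop_fluxtrend("reference contribution is zero: ratio undefined")
  if (a == 0) {
    return(list(percent = 0, percent_se = 100 * sa / abs(b)))
  }
  pct <- 100 * abs(a / b)
  list(percent = pct, percent_se = pct * sqrt((sa / a)^2 + (sb / b)^2))
}
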