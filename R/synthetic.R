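#' Configuration for the synthetic flux-panel generator
#'
#' Builds a validated configuration for [generate_drivers()] and
#' [generate_fluxes()]. Defaults emulate the observed study conditions of a
#' 23-site temperate/boreal flux network: staggered 10-20 year site records
#' within 1992-2013, a shared atmospheric CO2 series rising by about
#' 2 ppm yr^-1, wet sulphur deposition declining by about 4.6 % yr^-1 and wet
#' nitrogen deposition by about 1.1 % yr^-1, stationary temperature and drought
#' (SPEI), site-level random intercepts and trend slopes, and AR(1) residuals.
#'
#' @param n_sites number of sites (>= 2).
#' @param year_range inclusive calendar-year interval, length 2.
#' @param site_span min/max series length in years (min >= 3).
#' @param co2_start shared CO2 level (ppm) in the first year of `year_range`.
#' @param co2_trend linear CO2 increase (ppm yr^-1).
#' @param co2_sd sd of the iid noise around the CO2 ramp (ppm).
#' @param sdep_site_means range (kg S ha^-1 yr^-1) from which site-mean S
#'   deposition levels are drawn uniformly.
#' @param sdep_rel_trend relative S-deposition trend (fraction yr^-1, negative
#'   for decline).
#' @param sdep_sd lognormal noise sd (log scale) on deposition values.
#' @param ndep_site_means,ndep_rel_trend,ndep_sd same for N deposition.
#' @param dep_trend_type `"geometric"` (constant relative rate, the default) or
#'   `"linear"` decline of deposition.
#' @param mat_site_means range (degrees C) of site-mean annual temperature.
#' @param mat_sd marginal sd of interannual MAT variation (degrees C).
#' @param map_site_means range (mm) of site-mean annual precipitation.
#' @param map_cv coefficient of variation of interannual MAP.
#' @param spei_sd marginal sd of SPEI (dimensionless, nominally 1).
#' @param climate_ar1 lag-1 autocorrelation of MAT and SPEI (|.| < 1).
#' @param lai_site_means range (m^2 m^-2) of site-mean maximum LAI.
#' @param true_beta named list of ground-truth sensitivities, one numeric
#'   vector per response (`NEP`, `GPP`, `Re`, `LAI`), each named by driver
#'   (`CO2`, `Sdep`, `Ndep`, `MAT`, `SPEI`, and `LAI` for the flux responses):
#'   response units per driver unit.
#' @param flux_site_means,flux_level_sd mean and sd of across-site flux levels
#'   (g C m^-2 yr^-1), named by flux.
#' @param random_intercept_sd,random_slope_sd sd of site random intercepts
#'   (response units) and random year-slopes (response units yr^-1), named by
#'   response (including `LAI`).
#' @param resid_sd marginal sd of the AR(1) residuals, named by response.
#' @param resid_ar1 lag-1 autocorrelation of residuals (|.| < 1).
#' @param seed integer seed; `NULL` leaves the RNG state untouched.
#' @return A list of class `sim_config`.
#' @seealso [simulate_panel()]
#' @export
sim_config <- function(n_sites = 23,
                       year_range = c(1992, 2013),
                       site_span = c(10, 20),
                       co2_start = 356,
                       co2_trend = 2.0,
                       co2_sd = 0.5,
                       sdep_site_means = c(0.5, 4),
                       sdep_rel_trend = -0.046,
                       sdep_sd = 0.05,
                       ndep_site_means = c(3, 12),
                       ndep_rel_trend = -0.011,
                       ndep_sd = 0.05,
                       dep_trend_type = c("geometric", "linear"),
                       mat_site_means = c(2, 12),
                       mat_sd = 0.7,
                       map_site_means = c(500, 1300),
                       map_cv = 0.15,
                       spei_sd = 1,
                       climate_ar1 = 0.3,
                       lai_site_means = c(2, 6),
                       true_beta = list(
                         NEP = c(CO2 = 4.8,  Sdep = 24,     Ndep = 0, MAT = 0, SPEI = 0, LAI = 0),
                         GPP = c(CO2 = 4.49, Sdep = -31.24, Ndep = 0, MAT = 0, SPEI = 0, LAI = 0),
                         Re  = c(CO2 = 0,    Sdep = -74.01, Ndep = 0, MAT = 0, SPEI = 0, LAI = 0),
                         LAI = c(CO2 = 0.0095, Sdep = 0,    Ndep = 0, MAT = 0, SPEI = 0)
                       ),
                       flux_site_means = c(NEP = 350, GPP = 1400, Re = 1050),
                       flux_level_sd = c(NEP = 150, GPP = 300, Re = 250),
                       random_intercept_sd = c(NEP = 10, GPP = 15, Re = 15, LAI = 0.05),
                       random_slope_sd = c(NEP = 5, GPP = 6, Re = 6, LAI = 0.01),
                       resid_sd = c(NEP = 50, GPP = 70, Re = 60, LAI = 0.15),
                       resid_ar1 = 0.3,
                       seed = NULL) {
  dep_trend_type <- match.arg(dep_trend_type)
  cfg <- list(
    n_sites = n_sites, year_range = year_range, site_span = site_span,
    co2_start = co2_start, co2_trend = co2_trend, co2_sd = co2_sd,
    sdep_site_means = sdep_site_means, sdep_rel_trend = sdep_rel_trend,
    sdep_sd = sdep_sd,
    ndep_site_means = ndep_site_means, ndep_rel_trend = ndep_rel_trend,
    ndep_sd = ndep_sd,
    dep_trend_type = dep_trend_type,
    mat_site_means = mat_site_means, mat_sd = mat_sd,
    map_site_means = map_site_means, map_cv = map_cv,
    spei_sd = spei_sd, climate_ar1 = climate_ar1,
    lai_site_means = lai_site_means,
    true_beta = true_beta,
    flux_site_means = flux_site_means, flux_level_sd = flux_level_sd,
    random_intercept_sd = random_intercept_sd,
    random_slope_sd = random_slope_sd,
    resid_sd = resid_sd, resid_ar1 = resid_ar1,
    seed = seed
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_sites < 2) stop_fluxtrend("invalid sim_config: n_sites must be >= 2")
  if (length(cfg$year_range) != 2 || cfg$year_range[2] < cfg$year_range[1])
    stop_fluxtrend("invalid sim_config: year_range must be an increasing pair")
  if (cfg$site_span[1] < 3)
    stop_fluxtrend("invalid sim_config: site_span minimum must be >= 3")
  if (cfg$site_span[2] < cfg$site_span[1])
    stop_fluxtrend("invalid sim_config: site_span must be ordered min <= max")
  if (cfg$site_span[2] > diff(cfg$year_range) + 1)
    stop_fluxtrend("invalid sim_config: site_span maximum exceeds year_range width")
  if (abs(cfg$resid_ar1) >= 1)
    stop_fluxtrend("invalid sim_config: |resid_ar1| must be < 1")
  if (abs(cfg$climate_ar1) >= 1)
    stop_fluxtrend("invalid sim_config: |climate_ar1| must be < 1")
  sds <- c(cfg$co2_sd, cfg$sdep_sd, cfg$ndep_sd, cfg$mat_sd, cfg$map_cv,
           cfg$spei_sd, cfg$flux_level_sd, cfg$random_intercept_sd,
           cfg$random_slope_sd, cfg$resid_sd)
  if (any(sds < 0))
    stop_fluxtrend("invalid sim_config: all standard deviations must be >= 0")
  responses <- c("NEP", "GPP", "Re", "LAI")
  if (!all(responses %in% names(cfg$true_beta)))
    stop_fluxtrend("invalid sim_config: true_beta needs entries for NEP, GPP, Re, LAI")
  invisible(TRUE)
}

#' Generate the driver columns of a synthetic site-year panel
#'
#' Draws the environmental drivers only: a single CO2 series shared by all
#' sites (linear ramp plus iid noise), multiplicatively declining S and N
#' deposition from site-specific mean levels, and stationary AR(1) MAT, MAP and
#' SPEI around site means. Every site occupies a contiguous block of years
#' placed uniformly within `year_range`.
#'
#' @param config a [sim_config()] object.
#' @return A data.frame with columns `site`, `year`, `CO2`, `Sdep`, `Ndep`,
#'   `MAT`, `MAP`, `SPEI`, carrying the drawn site means and year windows as
#'   attributes for [generate_fluxes()].
#' @export
generate_drivers <- function(config) {
  validate_sim_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  y0 <- config$year_range[1]
  y1 <- config$year_range[2]
  sites <- sprintf("S%02d", seq_len(config$n_sites))

  # shared CO2 series over the whole window
  all_years <- y0:y1
  co2 <- config$co2_start + config$co2_trend * (all_years - y0) +
    rnorm(length(all_years), 0, config$co2_sd)

  span <- config$site_span
  n_years <- if (span[1] == span[2]) {
    rep(span[1], config$n_sites)
  } else {
    sample(span[1]:span[2], config$n_sites, replace = TRUE)
  }
  starts <- vapply(n_years, function(n) {
    last_start <- y1 - n + 1
    if (last_start == y0) y0 else sample(y0:last_start, 1L)
  }, numeric(1))

  unif <- function(rng, n) runif(n, rng[1], rng[2])
  site_means <- data.frame(
    site = sites,
    Sdep = unif(config$sdep_site_means, config$n_sites),
    Ndep = unif(config$ndep_site_means, config$n_sites),
    MAT  = unif(config$mat_site_means, config$n_sites),
    MAP  = unif(config$map_site_means, config$n_sites),
    LAI  = unif(config$lai_site_means, config$n_sites),
    stringsAsFactors = FALSE
  )

  dep_series <- function(mean_level, years, rel_trend, sd) {
    scale <- if (config$dep_trend_type == "geometric") {
      (1 + rel_trend)^(years - y0)
    } else {
      pmax(0, 1 + rel_trend * (years - y0))
    }
    mean_level * scale * exp(rnorm(length(years), 0, sd))
  }

  rows <- vector("list", config$n_sites)
  for (i in seq_len(config$n_sites)) {
    yrs <- seq(starts[i], length.out = n_years[i])
    n <- length(yrs)
    rows[[i]] <- data.frame(
      site = sites[i],
      year = yrs,
      CO2  = co2[match(yrs, all_years)],
      Sdep = dep_series(site_means$Sdep[i], yrs, config$sdep_rel_trend, config$sdep_sd),
      Ndep = dep_series(site_means$Ndep[i], yrs, config$ndep_rel_trend, config$ndep_sd),
      MAT  = site_means$MAT[i] + ar1_series(n, config$climate_ar1, config$mat_sd),
      MAP  = pmax(0, site_means$MAP[i] *
                    (1 + ar1_series(n, config$climate_ar1, config$map_cv))),
      SPEI = ar1_series(n, config$climate_ar1, config$spei_sd),
      stringsAsFactors = FALSE
    )
  }
  panel <- do.call(rbind, rows)
  rownames(panel) <- NULL
  attr(panel, "site_means") <- site_means
  attr(panel, "config_fingerprint") <- sim_fingerprint(config)
  panel
}

sim_fingerprint <- function(config) {
  paste(config$n_sites, config$year_range[1], config$year_range[2],
        config$site_span[1], config$site_span[2], sep = "/")
}

#' Generate flux and LAI responses on top of synthetic drivers
#'
#' Adds maximum LAI and the three flux responses (NEP, GPP, Re) to a driver
#' panel. Each response anomaly is a linear, interaction-free combination of
#' the within-site driver anomalies (coefficients `true_beta`), plus a site
#' random intercept, a site random year-slope, and stationary AR(1) noise;
#' responses are reported on the original scale (anomaly + site level). LAI is
#' generated first by the same machinery, so its anomalies can act as a
#' covariate for the fluxes. The per-driver ground-truth contributions to each
#' response trend (`true_beta[j]` times the realized mean within-site trend of
#' driver `j`) are stored in the `"ground_truth"` attribute.
#'
#' @param config the same [sim_config()] used for the drivers.
#' @param drivers output of [generate_drivers()].
#' @return The panel with added columns `LAI`, `NEP`, `GPP`, `Re`, their
#'   anomaly (`_an`) and site-mean (`_c`) columns, anomaly columns for all
#'   drivers, and attributes `ground_truth` and `random_effects`.
#' @export
generate_fluxes <- function(config, drivers) {
  validate_sim_config(config)
  check_columns(drivers, c("site", "year", "CO2", "Sdep", "Ndep", "MAT", "MAP", "SPEI"),
                "driver panel")
  if (!identical(attr(drivers, "config_fingerprint"), sim_fingerprint(config)))
    stop_fluxtrend("driver panel does not match config: site/year coverage differs")
  if (!is.null(config$seed)) set.seed(config$seed + 1L)

  panel <- drivers
  panel <- compute_anomalies(panel, c("CO2", "Sdep", "Ndep", "MAT", "SPEI"))
  site_ids <- unique(panel$site)
  site_rows <- split(seq_len(nrow(panel)), panel$site)[site_ids]

  site_means <- attr(drivers, "site_means")
  lai_level <- setNames(site_means$LAI, site_means$site)
  flux_level <- lapply(c(NEP = "NEP", GPP = "GPP", Re = "Re"), function(r) {
    setNames(rnorm(length(site_ids), config$flux_site_means[[r]],
                   config$flux_level_sd[[r]]), site_ids)
  })

  driver_cols <- c(CO2 = "CO2_an", Sdep = "Sdep_an", Ndep = "Ndep_an",
                   MAT = "MAT_an", SPEI = "SPEI_an", LAI = "LAI_an")

  random_effects <- list()
  add_response <- function(panel, resp, level_by_site) {
    beta <- config$true_beta[[resp]]
    b0 <- rnorm(length(site_ids), 0, config$random_intercept_sd[[resp]])
    b1 <- rnorm(length(site_ids), 0, config$random_slope_sd[[resp]])
    names(b0) <- names(b1) <- site_ids
    vals <- numeric(nrow(panel))
    for (s in site_ids) {
      idx <- site_rows[[s]]
      yrs <- panel$year[idx]
      det <- rep(0, length(idx))
      for (j in names(beta)) {
        col <- driver_cols[[j]]
        if (!col %in% names(panel)) next  # LAI anomalies absent for LAI itself
        det <- det + beta[[j]] * panel[[col]][idx]
      }
      noise <- ar1_series(length(idx), config$resid_ar1, config$resid_sd[[resp]])
      vals[idx] <- level_by_site[[s]] + det +
        b0[[s]] + b1[[s]] * (yrs - mean(yrs)) + noise
    }
    panel[[resp]] <- vals
    random_effects[[resp]] <<- data.frame(site = site_ids, intercept = b0,
                                          slope = b1, row.names = NULL)
    compute_anomalies(panel, resp)
  }

  panel <- add_response(panel, "LAI", lai_level)
  for (resp in c("NEP", "GPP", "Re")) {
    panel <- add_response(panel, resp, flux_level[[resp]])
  }

  # realized mean within-site OLS trend of each driver
  ols_slope <- function(y, t) {
    tc <- t - mean(t)
    sum(tc * y) / sum(tc^2)
  }
  realized_trend <- vapply(names(driver_cols), function(j) {
    col <- sub("_an$", "", driver_cols[[j]])
    mean(vapply(site_ids, function(s) {
      idx <- site_rows[[s]]
      ols_slope(panel[[col]][idx], panel$year[idx])
    }, numeric(1)))
  }, numeric(1))

  ground_truth <- lapply(config$true_beta, function(beta) {
    drv <- names(beta)
    data.frame(driver = drv,
               beta = as.numeric(beta),
               driver_trend = realized_trend[drv],
               contribution = as.numeric(beta) * realized_trend[drv],
               row.names = NULL)
  })

  attr(panel, "ground_truth") <- ground_truth
  attr(panel, "random_effects") <- random_effects
  panel
}

#' Simulate a complete synthetic flux panel
#'
#' Convenience wrapper running [generate_drivers()] then [generate_fluxes()].
#'
#' @param config a [sim_config()] object.
#' @return The synthetic panel (see [generate_fluxes()]).
#' @examples
#' panel <- simulate_panel(sim_config(n_sites = 4, seed = 1))
#' head(panel[, c("site", "year", "NEP", "CO2", "Sdep")])
#' @export
simulate_panel <- function(config = sim_config()) {
  generate_fluxes(config, generate_drivers(config))
}
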