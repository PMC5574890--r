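#' Read a site-year panel from a delimited text file
#'
#' A panel is a tidy table with one row per site and year. The reader checks
#' that required columns are present, that years are integral, and that
#' `(site, year)` pairs are unique; unknown columns are preserved.
#'
#' @param path file path.
#' @param required columns that must be present (beyond `site` and `year`).
#' @param sep field separator (default comma).
#' @return A data.frame with `site` as character and `year` as integer.
#' @export
read_panel <- function(path, required = character(), sep = ",") {
  panel <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
  check_columns(panel, c("site", "year", required), "panel file")
  panel$site <- as.character(panel$site)
  if (any(panel$year != round(panel$year), na.rm = TRUE))
    stop_fluxtrend("panel file has non-integral years")
  panel$year <- as.integer(panel$year)
  dup <- duplicated(panel[, c("site", "year")])
  if (any(dup)) {
    offenders <- unique(paste0(panel$site[dup], "/", panel$year[dup]))
    stop_fluxtrend("duplicate (site, year) rows: ",
                   paste(offenders, collapse = ", "))
  }
  panel
}

#' Write a site-year panel to a delimited text file
#'
#' Values round-trip through [read_panel()] at full double precision.
#'
#' @param panel a panel data.frame.
#' @param path file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, sep = ",") {
  check_columns(panel, c("site", "year"), "panel")
  out <- as.data.frame(lapply(panel, function(x) {
    if (is.double(x)) format(x, digits = 17, trim = TRUE, scientific = FALSE) else x
  }), check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Compute within-site anomalies and site means
#'
#' For each requested column and each site, the site mean over that site's
#' observed (non-missing) years is stored in `<col>_c`, and the anomaly --
#' annual value minus site mean -- in `<col>_an`. Missing cells are excluded
#' from the mean and stay missing in the anomaly column; a column that is
#' all-missing within a site yields missing mean and anomalies.
#'
#' @param panel a panel data.frame with `site` and `year`.
#' @param columns character vector of columns to centre.
#' @return The panel with added/overwritten `_c` and `_an` columns.
#' @examples
#' p <- data.frame(site = "a", year = 1:3, x = c(10, 12, 14))
#' compute_anomalies(p, "x")$x_an  # -2 0 2
#' @export
compute_anomalies <- function(panel, columns) {
  check_columns(panel, c("site", "year", columns), "panel")
  for (col in columns) {
    means <- tapply(panel[[col]], panel$site, function(x) mean(x, na.rm = TRUE))
    means[is.nan(means)] <- NA_real_
    m <- as.numeric(means[panel$site])
    panel[[paste0(col, "_c")]] <- m
    panel[[paste0(col, "_an")]] <- panel[[col]] - m
  }
  panel
}

#' Quality-control and gap-fill an annual CO2 series
#'
#' Tower CO2 records sometimes contain implausible annual values. A value is
#' flagged when it breaks plausible monotone growth: (i) a spike -- the
#' year-over-year increase exceeds `jump_factor` times the normal worldwide
#' increase of ~2 ppm and the value also exceeds its successor; (ii) a dip --
#' the value lies below its predecessor and below its successor (or below its
#' predecessor at the end of the series). Spikes are removed first and dips
#' re-evaluated on the remaining values, so a single bad year does not drag
#' its neighbours down with it. Flagged values are removed and filled with a
#' univariate penalized-spline smooth (generalized cross-validation) fitted to
#' the retained values. When fewer than `min_points` values remain, the
#' reference series (e.g. a background station record) is substituted if
#' supplied; otherwise the values stay missing.
#'
#' @param years integer years (gaps allowed).
#' @param co2 annual CO2 values (ppm), may contain `NA`.
#' @param reference optional data.frame with columns `year` and `CO2` used as
#'   fallback.
#' @param jump_factor multiple of `normal_increase` above which a year-on-year
#'   increase is implausible (default 3).
#' @param normal_increase typical annual CO2 increase, ppm (default 2).
#' @param min_points minimum retained values needed to fit the smoother.
#' @return A data.frame with columns `year`, `co2` (cleaned), `flag`
#'   (`"ok"`, `"spike"`, `"dip"`, `"filled"`, `"reference"`, `"unfilled"`),
#'   and `original`.
#' @export
qc_fill_co2 <- function(years, co2, reference = NULL,
                        jump_factor = 3, normal_increase = 2,
                        min_points = 4) {
  stopifnot(length(years) == length(co2))
  ord <- order(years)
  years <- years[ord]; co2 <- co2[ord]
  n <- length(co2)
  flag <- rep("ok", n)
  flag[is.na(co2)] <- "missing"
  threshold <- jump_factor * normal_increase

  # Adjacent retained values must not decrease (rule i/ii) and must not jump
  # by more than the threshold (rule iii). When violations exist, the value
  # participating in most violated pairs is removed and the checks repeated,
  # so a single bad year does not drag its neighbours down with it. Ties are
  # broken by distance from the robust (Theil-Sen) line of the retained values.
  retained <- which(!is.na(co2))
  repeat {
    if (length(retained) < 2) break
    v <- co2[retained]
    d <- diff(v)
    decrease <- d < 0
    jump <- d > threshold
    violated <- decrease | jump
    if (!any(violated)) break
    counts <- numeric(length(retained))
    for (k in which(violated)) {
      counts[k] <- counts[k] + 1
      counts[k + 1L] <- counts[k + 1L] + 1
    }
    worst <- which(counts == max(counts))
    if (length(worst) > 1L) {
      if (length(retained) >= 3L) {
        ts_fit <- theil_sen(years[retained], v)
        residual <- abs(v - (ts_fit$intercept + ts_fit$slope * years[retained]))
        worst <- worst[order(-residual[worst], -worst)][1L]
      } else {
        worst <- worst[length(worst)]
      }
    }
    drop_idx <- retained[worst]
    # classify: above the next retained value (or a large jump) => spike
    pos <- which(retained == drop_idx)
    nxt <- if (pos < length(retained)) retained[pos + 1L] else NA_integer_
    prev <- if (pos > 1L) retained[pos - 1L] else NA_integer_
    is_spike <- (!is.na(nxt) && co2[drop_idx] > co2[nxt]) ||
      (!is.na(prev) && co2[drop_idx] - co2[prev] > threshold)
    flag[drop_idx] <- if (is_spike) "spike" else "dip"
    retained <- setdiff(retained, drop_idx)
  }

  cleaned <- co2
  bad <- flag %in% c("spike", "dip")
  cleaned[bad] <- NA_real_
  to_fill <- which(is.na(cleaned))
  retained <- which(!is.na(cleaned))

  if (length(to_fill) > 0) {
    if (length(retained) >= min_points) {
      kdim <- max(3, min(length(retained) - 1, 10))
      fit <- mgcv::gam(y ~ s(x, k = kdim),
                       data = data.frame(x = years[retained], y = cleaned[retained]),
                       method = "GCV.Cp")
      pred <- as.numeric(predict(fit, newdata = data.frame(x = years[to_fill])))
      cleaned[to_fill] <- pred
      flag[to_fill] <- "filled"
    } else if (!is.null(reference)) {
      check_columns(reference, c("year", "CO2"), "reference series")
      idx <- match(years[to_fill], reference$year)
      cleaned[to_fill] <- reference$CO2[idx]
      flag[to_fill] <- ifelse(is.na(idx), "unfilled", "reference")
    } else {
      flag[to_fill] <- "unfilled"
      warning("fewer than ", min_points,
              " plausible CO2 values and no reference series: gaps left unfilled")
    }
  }

  data.frame(year = years, co2 = cleaned, flag = flag, original = co2,
             stringsAsFactors = FALSE)
}

#' Corrected maturity age of a forest stand
#'
#' The ratio of mean stand age to the species' logging maturity age: an index
#' of stand development (1 = at logging maturity).
#'
#' @param stand_age stand age, years (> 0).
#' @param logging_maturity_age logging maturity age, years (> 0).
#' @return The quotient (report to two decimals in tabular output).
#' @examples
#' corrected_maturity_age(118, 95) # 1.242...
#' @export
corrected_maturity_age <- function(stand_age, logging_maturity_age) {
  if (any(stand_age <= 0) || any(logging_maturity_age <= 0))
    stop_fluxtrend("stand_age and logging_maturity_age must be positive")
  stand_age / logging_maturity_age
}

#' Cumulative deposition over the preceding years
#'
#' For each site-year `t`, the sum of a deposition column over the years
#' `t - window` to `t - 1` within the same site. In `"strict"` mode the sum is
#' missing when any contributing year is absent from the panel (or missing);
#' in `"lenient"` mode available years are summed.
#'
#' @param panel a panel data.frame.
#' @param column deposition column name.
#' @param window number of preceding years (>= 1, default 5).
#' @param mode `"strict"` (default) or `"lenient"`.
#' @return The panel with an added column `<column>_cum<window>`.
#' @export
cumulative_deposition <- function(panel, column, window = 5,
                                  mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  if (window < 1) stop_fluxtrend("window must be >= 1")
  check_columns(panel, c("site", "year", column), "panel")
  out_col <- paste0(column, "_cum", window)
  panel[[out_col]] <- NA_real_
  for (s in unique(panel$site)) {
    idx <- which(panel$site == s)
    yrs <- panel$year[idx]
    vals <- panel[[column]][idx]
    for (k in seq_along(idx)) {
      want <- (yrs[k] - window):(yrs[k] - 1)
      got <- match(want, yrs)
      contrib <- vals[got]
      if (mode == "strict") {
        if (any(is.na(got)) || any(is.na(contrib))) next
        panel[[out_col]][idx[k]] <- sum(contrib)
      } else {
        if (all(is.na(contrib))) next
        panel[[out_col]][idx[k]] <- sum(contrib, na.rm = TRUE)
      }
    }
  }
  panel
}

#' Aggregate monthly climate records to warm-season annual values
#'
#' Averages temperature and SPEI and sums precipitation over the warm half of
#' the year (April-September) of each calendar year.
#'
#' @param monthly data.frame with columns `year`, `month`, and any of `MAT`,
#'   `MAP`, `SPEI` (plus optional `site`).
#' @param min_frac minimum fraction of the six warm-season months that must be
#'   present for a value to be reported (default 1, i.e. all six).
#' @return A data.frame with one row per (site-)year and columns
#'   `MAT_warm`, `MAP_warm`, `SPEI_warm` for those inputs present.
#' @export
warm_season_aggregate <- function(monthly, min_frac = 1) {
  check_columns(monthly, c("year", "month"), "monthly table")
  warm <- monthly[monthly$month %in% 4:9, , drop = FALSE]
  keys <- c(if ("site" %in% names(monthly)) "site", "year")
  groups <- split(warm, warm[keys], drop = TRUE)
  agg_one <- function(g) {
    res <- g[1, keys, drop = FALSE]
    for (col in intersect(c("MAT", "MAP", "SPEI"), names(monthly))) {
      x <- g[[col]][!is.na(g[[col]])]
      ok <- length(x) >= min_frac * 6
      res[[paste0(col, "_warm")]] <- if (!ok) NA_real_
        else if (col == "MAP") sum(x) else mean(x)
    }
    res
  }
  out <- do.call(rbind, lapply(groups, agg_one))
  rownames(out) <- NULL
  out[order(if ("site" %in% keys) out$site else "", out$year), , drop = FALSE]
}
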