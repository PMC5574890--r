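# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fluxtrend <- function(...) stop(..., call. = FALSE)

check_columns <- function(data, columns, what = "panel") {
  missing <- setdiff(columns, names(data))
  if (length(missing) > 0L) {
    stop_fluxtrend(sprintf("%s is missing required column(s): %s",
                           what, paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

# AR(1) correlation matrix for (possibly gapped) integer time points:
# entry (i, j) = phi^|t_i - t_j|
ar1_correlation <- function(times, phi) {
  stopifnot(abs(phi) < 1)
  d <- abs(outer(times, times, "-"))
  phi^d
}

# AICc from a log-likelihood, parameter count and sample size
aicc_value <- function(loglik, k, n) {
  if (n - k - 1 <= 0) {
    stop_fluxtrend(sprintf(
      "AICc undefined: need n - k - 1 > 0 (n = %d, k = %d)", n, k))
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Small-sample correction of an AIC value
#'
#' Converts an ordinary AIC into the second-order criterion
#' `AICc = AIC + 2k(k+1)/(n-k-1)`, where `k` is the number of estimated
#' parameters and `n` the number of observations.
#'
#' @param aic AIC value.
#' @param k number of estimated parameters (including variance parameters).
#' @param n number of observations.
#' @return The AICc value.
#' @examples
#' aicc_from_aic(100, k = 3, n = 20) # 101.5
#' @export
aicc_from_aic <- function(aic, k, n) {
  if (n - k - 1 <= 0) {
    stop_fluxtrend(sprintf(
      "AICc undefined: need n - k - 1 > 0 (n = %d, k = %d)", n, k))
  }
  aic + 2 * k * (k + 1) / (n - k - 1)
}

# stationary AR(1) series of length n with marginal sd `sd` and lag-1
# correlation `rho`; returns zeros when sd == 0
ar1_series <- function(n, rho, sd) {
  if (sd == 0 || n == 0L) return(rep(0, n))
  e <- numeric(n)
  e[1L] <- rnorm(1L, 0, sd)
  if (n > 1L) {
    innov_sd <- sd * sqrt(1 - rho^2)
    for (t in 2:n) e[t] <- rho * e[t - 1L] + rnorm(1L, 0, innov_sd)
  }
  e
}

# subtract the within-site mean from a series ("adjust all sites to the same
# mean"): removes between-site level differences so that per-site constant
# shifts carry exactly zero trend
center_by_site <- function(values, site) {
  m <- tapply(values, site, mean)
  values - as.numeric(m[as.character(site)])
}

# all permutations of 1..n as an n! x n matrix
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    shifted <- sub + (sub >= i)
    out[[i]] <- cbind(rep(i, nrow(sub)), shifted)
  }
  do.call(rbind, out)
}
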