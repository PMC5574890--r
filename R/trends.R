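#' Theil-Sen robust trend with a Mann-Kendall one-tailed test
#'
#' The slope is the median of all pairwise slopes `(y_j - y_i)/(t_j - t_i)`
#' (pairs with equal times excluded) and the intercept the median of
#' `y - slope * t`. The estimator has a breakdown point of about 29%, so
#' corrupting fewer than that fraction of points of an exact line leaves the
#' slope untouched. The one-tailed P value (H1: trend > 0) comes from the
#' Mann-Kendall S statistic, by default via the normal approximation with tie
#' and continuity corrections; for short untied series (`n <= exact_max`) the
#' exact permutation distribution of S is used instead. The standard error is
#' derived from the rank-based 95% confidence interval for Sen's slope
#' (interval half-width divided by 1.96).
#'
#' @param years time points (>= 3 pairs, >= 2 distinct).
#' @param values observations; pairs with missing entries are dropped.
#' @param exact `"auto"` (exact MK distribution when `n <= exact_max` and no
#'   ties), `"never"`, or `"always"` (errors if infeasible).
#' @param exact_max largest n for the exact distribution (default 10).
#' @return An object of class `trend_estimate`: a list with `slope`,
#'   `intercept`, `slope_se`, `p_one_tailed`, `n_years`, `method`, and the
#'   Mann-Kendall statistic `s` and its variance `var_s`.
#' @examples
#' theil_sen(1:3, c(1, 2, 3))$slope # 1
#' @export
theil_sen <- function(years, values, exact = c("auto", "never", "always"),
                      exact_max = 10) {
  exact <- match.arg(exact)
  ok <- !is.na(years) & !is.na(values)
  t <- as.numeric(years[ok]); y <- as.numeric(values[ok])
  n <- length(t)
  if (n < 3) stop_fluxtrend("theil_sen needs at least 3 paired observations")
  if (length(unique(t)) < 2) stop_fluxtrend("all years identical: no trend defined")
  ord <- order(t)
  t <- t[ord]; y <- y[ord]

  dt <- outer(t, t, "-"); dy <- outer(y, y, "-")
  lower <- lower.tri(dt)
  use <- lower & dt != 0
  slopes <- (dy / dt)[use]
  slope <- median(slopes)
  intercept <- median(y - slope * t)

  # Mann-Kendall S with tie-corrected variance
  s_stat <- sum(sign(dy[lower]) * sign(dt[lower]))
  tie_y <- table(y); tie_y <- tie_y[tie_y > 1]
  tie_t <- table(t); tie_t <- tie_t[tie_t > 1]
  tie_term <- function(x) sum(x * (x - 1) * (2 * x + 5))
  var_s <- (n * (n - 1) * (2 * n + 5) - tie_term(tie_y) - tie_term(tie_t)) / 18
  if (length(tie_y) && length(tie_t)) {
    var_s <- var_s +
      sum(tie_y * (tie_y - 1) * (tie_y - 2)) * sum(tie_t * (tie_t - 1) * (tie_t - 2)) /
        (9 * n * (n - 1) * (n - 2)) +
      sum(tie_y * (tie_y - 1)) * sum(tie_t * (tie_t - 1)) / (2 * n * (n - 1))
  }

  no_ties <- length(tie_y) == 0 && length(tie_t) == 0
  use_exact <- switch(exact,
    never = FALSE,
    auto = no_ties && n <= exact_max,
    always = {
      if (!no_ties) stop_fluxtrend("exact Mann-Kendall P requires untied data")
      if (n > exact_max) stop_fluxtrend("exact Mann-Kendall P limited to n <= ", exact_max)
      TRUE
    })

  if (use_exact) {
    p <- mk_exact_p_greater(n, s_stat)
  } else if (var_s == 0) {
    p <- 0.5
  } else {
    z <- if (s_stat > 0) (s_stat - 1) / sqrt(var_s)
         else if (s_stat < 0) (s_stat + 1) / sqrt(var_s)
         else 0
    p <- pnorm(z, lower.tail = FALSE)
  }

  structure(list(
    slope = slope, intercept = intercept,
    slope_se = sen_slope_se(slopes, var_s),
    p_one_tailed = p, n_years = n, method = "theil_sen",
    s = s_stat, var_s = var_s
  ), class = "trend_estimate")
}

# exact null distribution of Mann-Kendall S for untied data: S = N - 2D where
# D is the number of inversions of a random permutation (Mahonian counts)
mk_exact_p_greater <- function(n, s_obs) {
  counts <- 1
  for (k in 2:n) {                    # multiply generating polynomial by 1+q+...+q^(k-1)
    nc <- numeric(length(counts) + k - 1)
    for (j in 0:(k - 1)) {
      idx <- seq_along(counts) + j
      nc[idx] <- nc[idx] + counts
    }
    counts <- nc
  }                                   # counts[d + 1] = permutations with d inversions
  n_pairs <- n * (n - 1) / 2
  s_values <- n_pairs - 2 * (seq_along(counts) - 1)
  sum(counts[s_values >= s_obs]) / sum(counts)
}

# SE from the rank-based 95% CI for Sen's slope (Gilbert 1987)
sen_slope_se <- function(slopes, var_s) {
  ns <- length(slopes)
  sorted <- sort(slopes)
  if (ns < 2 || var_s <= 0) return(0)
  z <- qnorm(0.975)
  c_alpha <- z * sqrt(var_s)
  m1 <- max(1L, min(ns, as.integer(round((ns - c_alpha) / 2))))
  m2 <- max(1L, min(ns, as.integer(round((ns + c_alpha) / 2 + 1))))
  (sorted[m2] - sorted[m1]) / (2 * z)
}

#' @export
print.trend_estimate <- function(x, ...) {
  cat(sprintf("Trend (%s): %.4g +/- %.4g per year, one-tailed P = %.4g (n = %d)\n",
              x$method, x$slope, x$slope_se, x$p_one_tailed, x$n_years))
  invisible(x)
}

#' Summarise signs and significance of a set of per-site trends
#'
#' Counts sites with strictly positive slopes, and among those the sites whose
#' one-tailed P value falls below `alpha`.
#'
#' @param trends a list of [theil_sen()] results, or a data.frame with columns
#'   `slope` and `p_one_tailed`.
#' @param alpha significance level (default 0.05).
#' @return A list with `n`, `n_positive`, `n_nonpositive`,
#'   `n_significant_positive`, and `alpha`.
#' @export
trend_sign_summary <- function(trends, alpha = 0.05) {
  tab <- trends_to_table(trends)
  if (nrow(tab) == 0) stop_fluxtrend("empty trend list")
  pos <- !is.na(tab$slope) & tab$slope > 0
  sig <- pos & !is.na(tab$p_one_tailed) & tab$p_one_tailed < alpha
  list(n = sum(!is.na(tab$slope)),
       n_positive = sum(pos),
       n_nonpositive = sum(!pos & !is.na(tab$slope)),
       n_significant_positive = sum(sig),
       alpha = alpha)
}

trends_to_table <- function(trends) {
  if (is.data.frame(trends)) {
    check_columns(trends, c("slope", "p_one_tailed"), "trend table")
    return(trends)
  }
  data.frame(
    slope = vapply(trends, function(x) x$slope, numeric(1)),
    p_one_tailed = vapply(trends, function(x) x$p_one_tailed, numeric(1))
  )
}

#' Bootstrap test of the cross-site trend-sign distribution
#'
#' Tests whether the proportion of sites with increasing trends exceeds what
#' chance resampling of the observed slopes would give. The per-site slopes
#' are resampled with replacement `B` times; the statistic is the fraction of
#' positive slopes, and the P value is the proportion of resamples in which
#' that fraction is at most 0.5 (one-tailed, H1: the majority of sites is
#' increasing). Alternatively, `statistic = "sign_permutation"` flips the sign
#' of each slope with probability 1/2 and reports the proportion of sign
#' assignments with at least as many positives as observed.
#'
#' @param slopes numeric vector of per-site slopes (>= 2 sites).
#' @param B number of resamples (>= 1000).
#' @param seed optional integer seed.
#' @param statistic resampling scheme, see above.
#' @return A list with `boot_p`, `frac_positive` (observed), `B` and
#'   `statistic`.
#' @export
bootstrap_sign_test <- function(slopes, B = 10000, seed = NULL,
                                statistic = c("fraction_positive",
                                              "sign_permutation")) {
  statistic <- match.arg(statistic)
  slopes <- slopes[!is.na(slopes)]
  n <- length(slopes)
  if (n < 2) stop_fluxtrend("bootstrap_sign_test needs at least 2 sites")
  if (B < 1000) stop_fluxtrend("B must be >= 1000")
  if (!is.null(seed)) set.seed(seed)
  obs_frac <- mean(slopes > 0)
  if (statistic == "fraction_positive") {
    draws <- matrix(sample(slopes, n * B, replace = TRUE), nrow = B)
    frac <- rowMeans(draws > 0)
    p <- mean(frac <= 0.5)
  } else {
    signs <- matrix(sample(c(-1, 1), n * B, replace = TRUE), nrow = B)
    frac <- rowMeans(sweep(signs, 2, abs(slopes), `*`) > 0)
    p <- mean(frac >= obs_frac)
  }
  list(boot_p = p, frac_positive = obs_frac, B = B, statistic = statistic)
}

#' Kernel-density summary of a trend distribution
#'
#' Gaussian kernel density of per-site slopes (Silverman's rule-of-thumb
#' bandwidth unless supplied), with the fraction of density mass above zero --
#' the modelled percentage of sites with increasing trends.
#'
#' @param slopes numeric vector of per-site slopes (>= 2 distinct values).
#' @param bandwidth optional kernel bandwidth.
#' @param n grid size.
#' @return A list with `grid`, `density`, `bandwidth`, `frac_positive_mass`
#'   (in \[0, 1\]) and `frac_positive` (empirical).
#' @export
trend_density <- function(slopes, bandwidth = NULL, n = 512) {
  slopes <- slopes[!is.na(slopes)]
  if (length(unique(slopes)) < 2) {
    warning("degenerate trend distribution (all slopes equal): point mass")
    return(list(grid = unique(slopes), density = Inf, bandwidth = 0,
                frac_positive_mass = as.numeric(unique(slopes) > 0),
                frac_positive = mean(slopes > 0)))
  }
  d <- if (is.null(bandwidth)) density(slopes, n = n, cut = 4)
       else density(slopes, bw = bandwidth, n = n, cut = 4)
  trap <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  total <- trap(d$x, d$y)
  pos <- d$x > 0
  pos_mass <- if (any(pos)) trap(d$x[pos], d$y[pos]) else 0
  list(grid = d$x, density = d$y, bandwidth = d$bw,
       frac_positive_mass = pos_mass / total,
       frac_positive = mean(slopes > 0))
}
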