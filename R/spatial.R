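#' Forward selection of a weighted across-site regression
#'
#' Regresses a per-site quantity (typically a per-site trend) on site-level
#' characteristics by weighted least squares, weighting each site by its
#' number of observation years. Candidates are added greedily while the AICc
#' of the weighted fit improves (or, with `criterion = "p_enter"`, while the
#' best candidate's partial-F P value is below `alpha_in`). Interaction
#' candidates (`a:b`) are considered only once both parents are in the model
#' (marginality). Perfectly collinear candidates are skipped and logged.
#'
#' @param data data.frame with one row per site.
#' @param response response column.
#' @param candidates character vector of candidate terms (columns of `data`,
#'   possibly categorical, and `a:b` interactions).
#' @param weights positive per-site weights (default: column `n_years`).
#' @param criterion `"AICc"` (default) or `"p_enter"`.
#' @param alpha_in entry threshold for `criterion = "p_enter"`.
#' @return An object of class `spatial_model`: the final `lm` fit (`fit`),
#'   `selected` terms in entry order, `skipped` collinear candidates, `r2`
#'   (weighted), `vif` (see [vif_wls()]), and `importance` (PMVD shares,
#'   see [pmvd()], when the design allows it).
#' @export
forward_select_wls <- function(data, response, candidates,
                               weights = data$n_years,
                               criterion = c("AICc", "p_enter"),
                               alpha_in = 0.05) {
  criterion <- match.arg(criterion)
  if (is.null(weights)) stop_fluxtrend("weights are required (e.g. n_years per site)")
  if (any(weights <= 0)) stop_fluxtrend("weights must be positive")
  vars <- unique(unlist(strsplit(candidates, ":", fixed = TRUE)))
  check_columns(data, c(response, vars), "site table")
  dd <- data
  dd$.w <- weights
  n <- nrow(dd)

  fit_terms <- function(terms) {
    rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
    lm(as.formula(paste(response, "~", rhs)), data = dd, weights = .w)
  }
  crit <- function(fit) {
    k <- as.numeric(attr(logLik(fit), "df"))
    if (n - k - 1 <= 0) return(Inf)
    aicc_from_aic(AIC(fit), k, n)
  }

  selected <- character(0)
  skipped <- character(0)
  current <- fit_terms(selected)
  current_crit <- crit(current)
  repeat {
    pool <- setdiff(candidates, c(selected, skipped))
    # marginality for interactions
    pool <- pool[vapply(pool, function(tm) {
      p <- strsplit(tm, ":", fixed = TRUE)[[1]]
      length(p) == 1 || all(p %in% selected)
    }, logical(1))]
    if (length(pool) == 0) break
    trials <- lapply(pool, function(tm) {
      f <- tryCatch(fit_terms(c(selected, tm)), error = function(e) NULL)
      if (is.null(f) || anyNA(coef(f))) return(NULL)
      f
    })
    bad <- vapply(trials, is.null, logical(1))
    if (any(bad)) skipped <- c(skipped, pool[bad])
    pool <- pool[!bad]; trials <- trials[!bad]
    if (length(pool) == 0) break
    if (criterion == "AICc") {
      crits <- vapply(trials, crit, numeric(1))
      best <- which.min(crits)
      if (crits[best] >= current_crit) break
      selected <- c(selected, pool[best])
      current <- trials[[best]]
      current_crit <- crits[best]
    } else {
      pvals <- vapply(trials, function(f) {
        a <- stats::anova(current, f)
        a$`Pr(>F)`[2]
      }, numeric(1))
      best <- which.min(pvals)
      if (is.na(pvals[best]) || pvals[best] >= alpha_in) break
      selected <- c(selected, pool[best])
      current <- trials[[best]]
      current_crit <- crit(current)
    }
  }

  r2 <- weighted_r2(current, dd$.w)
  vif <- tryCatch(vif_wls(current), error = function(e) NULL)
  importance <- tryCatch(pmvd(current), error = function(e) NULL)
  structure(list(fit = current, selected = selected, skipped = skipped,
                 response = response, r2 = r2, vif = vif,
                 importance = importance, weights = weights),
            class = "spatial_model")
}

#' @export
print.spatial_model <- function(x, ...) {
  cat(sprintf("Weighted across-site model of %s (R2 = %.3f)\n",
              x$response, x$r2))
  cat("Selected terms:",
      if (length(x$selected)) paste(x$selected, collapse = ", ") else "(none)",
      "\n")
  print(summary(x$fit)$coefficients, digits = 4)
  if (!is.null(x$importance)) {
    cat("PMVD importance shares:\n"); print(round(x$importance, 4))
  }
  invisible(x)
}

weighted_r2 <- function(fit, w = fit$weights) {
  y <- fit$model[[1]]
  if (is.null(w)) w <- rep(1, length(y))
  e <- resid(fit)
  ybar <- weighted.mean(y, w)
  1 - sum(w * e^2) / sum(w * (y - ybar)^2)
}

#' Variance inflation factors of a (weighted) regression
#'
#' `VIF_j = 1/(1 - R2_j)`, where `R2_j` is the (weighted) coefficient of
#' determination of predictor `j` regressed on the remaining predictors. A
#' single-predictor model has VIF 1 by convention; near-perfect collinearity
#' is capped at `cap` and flagged with a warning.
#'
#' @param fit an `lm` fit (possibly weighted).
#' @param threshold warn when any VIF exceeds this level (default 10).
#' @param cap upper bound for reported VIFs (default 1e6).
#' @return Named numeric vector of VIFs, one per non-intercept column of the
#'   model matrix.
#' @export
vif_wls <- function(fit, threshold = 10, cap = 1e6) {
  X <- model.matrix(fit)
  has_int <- "(Intercept)" %in% colnames(X)
  pred <- setdiff(colnames(X), "(Intercept)")
  if (length(pred) == 0) stop_fluxtrend("no predictors in model")
  w <- fit$weights %||% rep(1, nrow(X))
  if (length(pred) == 1) return(setNames(1, pred))
  out <- vapply(pred, function(j) {
    others <- setdiff(pred, j)
    xf <- lm.wfit(x = cbind(if (has_int) 1, X[, others, drop = FALSE]),
                  y = X[, j], w = w)
    e <- xf$residuals
    xbar <- weighted.mean(X[, j], w)
    ss_tot <- sum(w * (X[, j] - xbar)^2)
    r2 <- 1 - sum(w * e^2) / ss_tot
    if (r2 >= 1 - 1 / cap) cap else 1 / (1 - r2)
  }, numeric(1))
  if (any(out >= cap))
    warning("near-perfect collinearity: VIF capped at ", cap, " for ",
            paste(names(out)[out >= cap], collapse = ", "))
  else if (any(out > threshold))
    warning("VIF above ", threshold, " for ",
            paste(names(out)[out > threshold], collapse = ", "))
  out
}

#' Proportional marginal variance decomposition (PMVD)
#'
#' Decomposes the (weighted) R2 of a regression into non-negative per-predictor
#' shares. Like LMG, PMVD averages the sequential R2 increment of each
#' predictor over orderings; unlike LMG the orderings carry data-dependent
#' weights proportional to `prod_i (R2_full - R2(first i))^{-1}`, which gives
#' the exclusion property: a predictor with a zero coefficient in the full
#' model receives a zero share. Shares sum to the full-model R2. The
#' enumeration over orderings is exhaustive, so the number of predictors is
#' limited to `max_predictors`; `method = "lmg"` (equal ordering weights) is
#' available as a fallback for larger models.
#'
#' @param fit an `lm` fit (possibly weighted) with numeric predictors.
#' @param method `"pmvd"` (default) or `"lmg"`.
#' @param max_predictors enumeration limit (default 10).
#' @return Named numeric vector of importance shares (summing to the
#'   full-model R2).
#' @export
pmvd <- function(fit, method = c("pmvd", "lmg"), max_predictors = 10) {
  method <- match.arg(method)
  X <- model.matrix(fit)
  pred <- setdiff(colnames(X), "(Intercept)")
  p <- length(pred)
  if (p == 0) stop_fluxtrend("no predictors in model")
  if (p > max_predictors)
    stop_fluxtrend("PMVD enumerates all orderings and is limited to ",
                   max_predictors, " predictors; use method = 'lmg'")
  y <- fit$model[[1]]
  w <- fit$weights %||% rep(1, nrow(X))
  ybar <- weighted.mean(y, w)
  ss_tot <- sum(w * (y - ybar)^2)

  r2_subset <- function(cols) {
    if (length(cols) == 0) return(0)
    xf <- lm.wfit(x = cbind(1, X[, cols, drop = FALSE]), y = y, w = w)
    1 - sum(w * xf$residuals^2) / ss_tot
  }
  # cache R2 of every subset by bitmask
  r2 <- numeric(2^p)
  for (mask in 0:(2^p - 1)) {
    cols <- pred[bitwAnd(mask, 2^(seq_len(p) - 1)) > 0]
    r2[mask + 1] <- r2_subset(cols)
  }
  full_mask <- 2^p - 1
  r2_full <- r2[full_mask + 1]

  # exclusion property: predictors whose removal leaves R2 unchanged (zero
  # coefficient in the full model) get share zero exactly (limit of the
  # PMVD weights); PMVD is then computed among the remaining predictors
  active <- seq_len(p)
  if (method == "pmvd") {
    drop_r2 <- vapply(seq_len(p), function(j)
      r2_full - r2[full_mask - 2^(j - 1) + 1], numeric(1))
    active <- which(drop_r2 > 1e-12 * max(r2_full, 1))
  }
  shares <- setNames(numeric(p), pred)
  if (length(active) == 0) return(shares)

  pa <- length(active)
  perms <- all_permutations(pa)
  r2a_full <- r2[sum(2^(active - 1)) + 1]
  total_weight <- 0
  acc <- numeric(pa)
  for (r in seq_len(nrow(perms))) {
    ord <- active[perms[r, ]]
    masks <- cumsum(2^(ord - 1))
    r2_seq <- c(0, r2[masks + 1])
    inc <- diff(r2_seq)
    wgt <- if (method == "lmg") 1 else {
      rem <- r2a_full - r2_seq[seq_len(pa)]    # remaining joint contribution
      rem <- rem[-1]                           # i = 1 .. pa-1
      if (pa == 1) 1 else 1 / prod(pmax(rem, 1e-300))
    }
    total_weight <- total_weight + wgt
    acc[match(ord, active)] <- acc[match(ord, active)] + wgt * inc
  }
  shares[active] <- acc / total_weight
  shares
}
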