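#' Fit a linear mixed model with site random effects and AR(1) residuals
#'
#' Fits a Gaussian linear mixed model of the kind used throughout the panel
#' analysis: fixed effects given by `fixed`, a site-level random intercept
#' and/or random slope in (centred) time, and an AR(1) correlation of
#' within-site residuals across years. Gapped years are handled with the
#' `phi^|delta year|` convention. Estimation is by ML or REML through the nlme
#' engine (`lme`, or `gls` when no random terms are requested). If the
#' requested random structure fails to converge, the random slope is dropped
#' and the fit retried, with the downgrade recorded in `notes`.
#'
#' @param data a panel data.frame.
#' @param response response column name.
#' @param fixed character vector of fixed-effect term labels (main effects and
#'   `a:b` interactions over columns of `data`, or the special term `".time_c"`
#'   for centred time). `NULL` fits an intercept-only model.
#' @param group grouping (site) column.
#' @param time integer time column used for the AR(1) structure and the random
#'   slope.
#' @param random any of `"intercept"`, `"slope"`; `NULL` for no random terms.
#' @param ar1 include the AR(1) residual correlation?
#' @param method `"ML"` or `"REML"`.
#' @return An object of class `lmm_fit`: a list with elements `beta`, `vcov`,
#'   `var_intercept`, `var_slope`, `phi`, `sigma2`, `loglik`, `n_obs`,
#'   `k_params`, `aicc`, `converged`, `notes`, plus bookkeeping needed by
#'   [predict_lmm()] and [refit_lmm()].
#' @export
fit_lmm <- function(data, response, fixed = NULL, group = "site",
                    time = "year", random = c("intercept", "slope"),
                    ar1 = TRUE, method = c("ML", "REML")) {
  method <- match.arg(method)
  if (!is.null(random)) random <- match.arg(random, several.ok = TRUE)
  vars <- unique(unlist(strsplit(fixed %||% character(), ":", fixed = TRUE)))
  vars <- setdiff(vars, ".time_c")
  cols <- unique(c(response, vars, group, time))
  check_columns(data, cols, "panel")
  dd <- data[complete.cases(data[, cols, drop = FALSE]), cols, drop = FALSE]
  dd[[group]] <- factor(dd[[group]])
  if (nlevels(dd[[group]]) < 2 && length(random) > 0)
    stop_fluxtrend("fit_lmm needs at least 2 groups for random effects")
  center <- mean(dd[[time]])
  dd$.time_c <- dd[[time]] - center
  rhs <- if (length(fixed %||% character()) == 0) "1" else paste(fixed, collapse = " + ")
  fml <- as.formula(paste(response, "~", rhs))

  corr <- NULL  # set per attempt below

  build_random <- function(r) {
    if (length(r) == 0) return(NULL)
    if ("slope" %in% r && "intercept" %in% r) {
      setNames(list(nlme::pdDiag(as.formula("~ .time_c"))), group)
    } else if (identical(sort(r), "slope")) {
      setNames(list(nlme::pdSymm(as.formula("~ .time_c - 1"))), group)
    } else {
      setNames(list(as.formula("~ 1")), group)
    }
  }

  attempt <- function(r) {
    if (length(r) > 0) {
      nlme::lme(fixed = fml, data = dd, random = build_random(r),
                correlation = corr, method = method,
                control = nlme::lmeControl(maxIter = 100, msMaxIter = 100,
                                           opt = "optim", returnObject = FALSE))
    } else {
      nlme::gls(model = fml, data = dd, correlation = corr, method = method,
                control = nlme::glsControl(maxIter = 100, msMaxIter = 100,
                                           returnObject = FALSE))
    }
  }

  plans <- list(random)
  if ("slope" %in% (random %||% character()))
    plans <- c(plans, list("intercept"))
  if (length(random %||% character()) > 0)
    plans <- c(plans, list(NULL))

  out <- NULL; used <- NULL; used_ar1 <- ar1; notes <- character()
  for (a in unique(c(ar1, FALSE))) {
    corr <- if (a) {
      nlme::corAR1(form = as.formula(paste0("~ ", time, " | ", group)))
    } else NULL
    for (r in plans) {
      # extraction (including the AICc sample-size requirement) is part of the
      # attempt: an over-parameterised structure must downgrade, not abort
      out <- tryCatch(
        extract_lmm(attempt(r), r, a, method, fml, fixed, response,
                    group, time, center, dd, notes),
        error = function(e) e)
      if (!inherits(out, "error")) { used <- r; used_ar1 <- a; break }
      notes <- c(notes, sprintf("fit with random = {%s}, ar1 = %s failed: %s",
                                paste(r %||% "none", collapse = ","), a,
                                conditionMessage(out)))
    }
    if (!inherits(out, "error")) break
  }
  if (inherits(out, "error"))
    stop_fluxtrend("fit_lmm did not converge under any random structure: ",
                   conditionMessage(out))
  if (!identical(used, random) || !identical(used_ar1, ar1)) {
    notes <- c(notes, "model structure downgraded")
    out$notes <- notes
  }
  out
}

extract_lmm <- function(fit, random, ar1, method, fml, fixed, response,
                        group, time, center, dd, notes) {
  is_lme <- inherits(fit, "lme")
  beta <- if (is_lme) nlme::fixef(fit) else coef(fit)
  vc <- as.matrix(vcov(fit))
  sigma2 <- fit$sigma^2
  phi <- if (ar1) {
    as.numeric(coef(fit$modelStruct$corStruct, unconstrained = FALSE))
  } else 0
  var_intercept <- 0; var_slope <- 0
  if (is_lme) {
    G <- try(nlme::getVarCov(fit), silent = TRUE)
    if (!inherits(G, "try-error")) {
      gn <- rownames(G)
      if ("(Intercept)" %in% gn) var_intercept <- G["(Intercept)", "(Intercept)"]
      if (".time_c" %in% gn) var_slope <- G[".time_c", ".time_c"]
    }
  }
  n <- nrow(dd)
  k <- length(beta) + sum(c("intercept", "slope") %in% (random %||% character())) +
    as.integer(ar1) + 1L
  ll <- as.numeric(logLik(fit))
  structure(list(
    beta = beta, vcov = vc,
    var_intercept = var_intercept, var_slope = var_slope,
    phi = phi, sigma2 = sigma2,
    loglik = ll, n_obs = n, k_params = k,
    aicc = aicc_value(ll, k, n),
    converged = TRUE, notes = notes,
    engine = fit, formula = fml, fixed_terms = fixed,
    response = response, group = group, time = time,
    random = random, ar1 = ar1, method = method,
    time_center = center, data = dd
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Linear mixed model (%s), %d obs, logLik %.3f, AICc %.3f\n",
              x$method, x$n_obs, x$loglik, x$aicc))
  cat("Fixed effects:\n")
  print(round(x$beta, 6))
  cat(sprintf("var(intercept) %.4g  var(slope) %.4g  phi %.4g  sigma2 %.4g\n",
              x$var_intercept, x$var_slope, x$phi, x$sigma2))
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Refit a mixed model with a different estimation method
#'
#' Used by the model-averaging stage, which ranks models under ML and reports
#' the retained set under REML.
#'
#' @param fit an [fit_lmm()] object.
#' @param method `"ML"` or `"REML"`.
#' @return A new `lmm_fit`.
#' @export
refit_lmm <- function(fit, method = "REML") {
  fit_lmm(fit$data, fit$response, fixed = fit$fixed_terms, group = fit$group,
          time = fit$time, random = fit$random, ar1 = fit$ar1, method = method)
}

#' Predict from a fitted mixed model
#'
#' Fixed-effect predictions `X beta`, optionally adding the empirical BLUPs of
#' the site random effects. Standard errors come from the fixed-effect
#' covariance (conditional on the estimated variance components). Sites absent
#' from the training data receive a zero random part and are flagged.
#'
#' @param fit an [fit_lmm()] object.
#' @param newdata data.frame with the model's columns.
#' @param include_random add site random effects?
#' @return A data.frame with columns `fit`, `se`, and `random_known`.
#' @export
predict_lmm <- function(fit, newdata, include_random = FALSE) {
  newdata$.time_c <- newdata[[fit$time]] - fit$time_center
  X <- model_matrix_lmm(fit, newdata)
  pred <- as.numeric(X %*% fit$beta)
  se <- sqrt(rowSums((X %*% fit$vcov) * X))
  random_known <- rep(TRUE, nrow(newdata))
  if (include_random && inherits(fit$engine, "lme")) {
    re <- nlme::ranef(fit$engine)
    sites <- as.character(newdata[[fit$group]])
    idx <- match(sites, rownames(re))
    random_known <- !is.na(idx)
    b0 <- if ("(Intercept)" %in% colnames(re)) re[["(Intercept)"]] else
      rep(0, nrow(re))
    b1 <- if (".time_c" %in% colnames(re)) re[[".time_c"]] else rep(0, nrow(re))
    add <- ifelse(random_known,
                  b0[idx] + b1[idx] * newdata$.time_c,
                  0)
    pred <- pred + add
    if (any(!random_known))
      warning("sites unseen during fitting received a zero random part: ",
              paste(unique(sites[!random_known]), collapse = ", "))
  }
  data.frame(fit = pred, se = se, random_known = random_known)
}

#' Second-order Akaike information criterion of a fitted model
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)`, where `k` counts fixed effects,
#' variance/correlation components, and the residual variance.
#'
#' @param fit an [fit_lmm()] object.
#' @return The AICc value.
#' @export
aicc <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  fit$aicc
}

# covariance structure of a fitted trend model, reusable as a fixed linear
# functional on other series (see gls_trend)
trend_structure <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  list(var_intercept = fit$var_intercept, var_slope = fit$var_slope,
       phi = fit$phi, sigma2 = fit$sigma2, time_center = fit$time_center)
}

# shared machinery of the fixed-structure GLS trend functional: per-site
# GLS blocks under the mixed-model covariance, with one fixed intercept per
# site plus the common slope. The slope is then estimated purely from
# within-site variation, and any per-site constant shift of the series is
# annihilated exactly (the "all sites adjusted to the same mean" convention).
gls_core <- function(years, site, struct) {
  tc <- years - struct$time_center
  # floor the residual variance so V stays invertible for noise-free series;
  # the GLS slope is insensitive to the floor when the structure is degenerate
  scale <- struct$var_intercept + struct$var_slope + struct$sigma2
  struct$sigma2 <- max(struct$sigma2, 1e-8 * scale, 1e-12)
  sites <- unique(site)
  S <- length(sites)
  p <- S + 1L
  XtVX <- matrix(0, p, p)
  blocks <- vector("list", S)
  for (si in seq_len(S)) {
    idx <- which(site == sites[si])
    Zi <- cbind(1, tc[idx])                 # random-effects design
    Xi <- matrix(0, length(idx), p)
    Xi[, si] <- 1
    Xi[, p] <- tc[idx]
    Ri <- ar1_correlation(years[idx], struct$phi)
    G <- diag(c(struct$var_intercept, struct$var_slope), 2)
    Vi <- Zi %*% G %*% t(Zi) + struct$sigma2 * Ri
    Wi <- solve(Vi)
    XtVX <- XtVX + t(Xi) %*% Wi %*% Xi
    blocks[[si]] <- list(idx = idx, XtW = t(Xi) %*% Wi)
  }
  list(cv = solve(XtVX), blocks = blocks, p = p, S = S, n = length(years))
}

# GLS estimate of the mean linear trend of (site, year, value) series under a
# FIXED mixed-model covariance structure. Because the variance parameters
# are held fixed, this is a linear functional of the values: essential for
# the exact additivity of the attribution decomposition.
gls_trend <- function(years, site, values, struct) {
  ok <- !is.na(values)
  years <- years[ok]; site <- site[ok]; values <- values[ok]
  core <- gls_core(years, site, struct)
  p <- core$p
  XtVy <- numeric(p)
  for (b in core$blocks) XtVy <- XtVy + b$XtW %*% values[b$idx]
  beta <- as.numeric(core$cv %*% XtVy)
  se <- sqrt(core$cv[p, p])
  structure(list(slope = beta[p], intercept = mean(beta[seq_len(core$S)]),
                 slope_se = se,
                 p_one_tailed = pnorm(beta[p] / se, lower.tail = FALSE),
                 n_years = length(values), method = "gls_fixed"),
            class = "trend_estimate")
}

# the slope of gls_trend as an explicit weight vector w (slope = sum(w * v)),
# used for delta-method error propagation of linear functionals of fitted
# coefficients
gls_slope_weights <- function(years, site, struct) {
  core <- gls_core(years, site, struct)
  w <- numeric(core$n)
  for (b in core$blocks) {
    w[b$idx] <- as.numeric(core$cv[core$p, , drop = FALSE] %*% b$XtW)
  }
  w
}

# fixed-effect design matrix of a fitted model evaluated on new data, with
# columns aligned to the coefficient vector
model_matrix_lmm <- function(fit, newdata) {
  newdata$.time_c <- newdata[[fit$time]] - fit$time_center
  tt <- stats::delete.response(terms(fit$formula, data = fit$data))
  X <- model.matrix(tt, newdata)
  X[, names(fit$beta), drop = FALSE]
}

#' Panel mean trend from a mixed model with AR(1) residuals
#'
#' The average trend across sites of an annual variable: the fixed effect of
#' (centred) year in a mixed model with site-level random intercepts and
#' random slopes and an AR(1) within-site residual correlation. The one-tailed
#' P value (H1: trend > 0) uses the large-sample normal ratio.
#'
#' @param panel a panel data.frame.
#' @param response column whose mean trend is wanted.
#' @param group,time,ar1,method,random passed to [fit_lmm()].
#' @return A `trend_estimate` (method `"lmm"`) whose `fit` element holds the
#'   underlying `lmm_fit`.
#' @export
mean_trend_lmm <- function(panel, response, group = "site", time = "year",
                           random = c("intercept", "slope"), ar1 = TRUE,
                           method = "REML") {
  fit <- fit_lmm(panel, response, fixed = ".time_c", group = group,
                 time = time, random = random, ar1 = ar1, method = method)
  slope <- unname(fit$beta[".time_c"])
  se <- sqrt(fit$vcov[".time_c", ".time_c"])
  p <- if (is.finite(se) && se > 0) {
    pnorm(slope / se, lower.tail = FALSE)
  } else if (slope > 0) 0 else if (slope < 0) 1 else 0.5
  structure(list(slope = slope, intercept = unname(fit$beta["(Intercept)"]),
                 slope_se = se,
                 p_one_tailed = p,
                 n_years = fit$n_obs, method = "lmm", fit = fit),
            class = "trend_estimate")
}
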