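#' Saturated anomaly/interaction model specification
#'
#' Builds the term set of the saturated model used to attribute flux (or LAI)
#' trends: four interaction blocks pairing a site-mean covariate, its annual
#' anomaly and CO2 -- `(mean Sdep + Sdep_an + CO2)`, `(mean Ndep + Ndep_an +
#' CO2)`, `(MATc + MAT_an + CO2)`, `(MAPc + SPEI + CO2)` -- with all pairwise
#' interactions within each block as candidates, plus the extra interactions
#' `mean Sdep x mean Ndep`, `MATc x MAPc` and `CO2 x stand age`. CO2 enters
#' once as a main effect even though it sits in every block. For flux
#' responses the LAI anomaly is added as a covariate (no interactions).
#'
#' @param response one of `"NEP"`, `"GPP"`, `"Re"`, `"LAI"`.
#' @param include_lai include the LAI-anomaly covariate (flux models only).
#' @param stand_age include the `CO2 x stand_age` interaction (requires a
#'   `stand_age` column).
#' @return A list with `response` (the anomaly column), `mains` and
#'   `interactions` (character vectors), suitable for [enumerate_models()].
#' @export
saturated_spec <- function(response = c("NEP", "GPP", "Re", "LAI"),
                           include_lai = NULL, stand_age = TRUE) {
  response <- match.arg(response)
  if (is.null(include_lai)) include_lai <- response != "LAI"
  blocks <- list(c("Sdep_c", "Sdep_an", "CO2"),
                 c("Ndep_c", "Ndep_an", "CO2"),
                 c("MATc", "MAT_an", "CO2"),
                 c("MAPc", "SPEI", "CO2"))
  mains <- unique(unlist(blocks))
  interactions <- unique(unlist(lapply(blocks, function(b) {
    apply(combn(b, 2), 2, function(p) paste(sort(p), collapse = ":"))
  })))
  interactions <- unique(c(interactions,
                           paste(sort(c("Sdep_c", "Ndep_c")), collapse = ":"),
                           paste(sort(c("MATc", "MAPc")), collapse = ":")))
  if (stand_age) {
    mains <- c(mains, "stand_age")
    interactions <- c(interactions, paste(sort(c("CO2", "stand_age")), collapse = ":"))
  }
  if (include_lai) mains <- c(mains, "LAI_an")
  list(response = paste0(response, "_an"), mains = mains,
       interactions = interactions)
}

canonical_interaction <- function(x) {
  vapply(strsplit(x, ":", fixed = TRUE),
         function(p) paste(sort(p), collapse = ":"), character(1))
}

#' Enumerate all admissible submodels of a term set
#'
#' Generates every subset of the main effects (including the intercept-only
#' model), and for each subset attaches every combination of the candidate
#' pairwise interactions. Under marginality (the default) an interaction is a
#' candidate only when both its parent main effects are present.
#'
#' @param mains character vector of main-effect terms.
#' @param interactions character vector of `a:b` interaction candidates.
#' @param marginality enforce the marginality constraint?
#' @param max_models abort (with an error suggesting constraints) if the
#'   enumeration would exceed this many models.
#' @return A list of character vectors of term labels, in a deterministic
#'   canonical order; the first element is the intercept-only model
#'   (`character(0)`).
#' @examples
#' length(enumerate_models(c("A", "B")))          # 4
#' length(enumerate_models(c("A", "B"), "A:B"))   # 5
#' @export
enumerate_models <- function(mains, interactions = character(),
                             marginality = TRUE, max_models = 1e5) {
  mains <- unique(mains)
  interactions <- unique(canonical_interaction(interactions))
  parents <- strsplit(interactions, ":", fixed = TRUE)
  bad <- vapply(parents, function(p)
    length(p) != 2 || !all(p %in% mains), logical(1))
  if (any(bad))
    stop_fluxtrend("interaction(s) with parents outside the main-effect set: ",
                   paste(interactions[bad], collapse = ", "))

  m <- length(mains)
  if (2^m > max_models)
    stop_fluxtrend("enumeration exceeds max_models (", max_models,
                   "): constrain the term set or raise the cap")
  # predicted count to fail fast before materialising
  count <- 0
  for (mask in 0:(2^m - 1)) {
    present <- mains[bitwAnd(mask, 2^(seq_len(m) - 1)) > 0]
    adm <- if (marginality) {
      sum(vapply(parents, function(p) all(p %in% present), logical(1)))
    } else length(interactions)
    count <- count + 2^adm
    if (count > max_models)
      stop_fluxtrend("enumeration exceeds max_models (", max_models,
                     "): constrain the term set or raise the cap")
  }

  models <- vector("list", count)
  k <- 0L
  for (mask in 0:(2^m - 1)) {
    present <- mains[bitwAnd(mask, 2^(seq_len(m) - 1)) > 0]
    adm <- if (marginality) {
      interactions[vapply(parents, function(p) all(p %in% present), logical(1))]
    } else interactions
    a <- length(adm)
    for (imask in 0:(2^a - 1)) {
      ints <- if (a == 0) character(0) else
        adm[bitwAnd(imask, 2^(seq_len(a) - 1)) > 0]
      k <- k + 1L
      models[[k]] <- c(present, ints)
    }
  }
  models
}

#' Fit every model of an enumerated set
#'
#' @param panel a panel data.frame.
#' @param response response column (typically an anomaly column).
#' @param models list of term-label vectors from [enumerate_models()].
#' @param method estimation method for ranking (default ML).
#' @param ... further arguments to [fit_lmm()] (`group`, `time`, `random`,
#'   `ar1`).
#' @return A list of `lmm_fit` objects (failed fits are kept as `NULL` with a
#'   warning).
#' @export
fit_model_set <- function(panel, response, models, method = "ML", ...) {
  fits <- vector("list", length(models))
  failed <- 0L
  for (i in seq_along(models)) {
    f <- tryCatch(
      fit_lmm(panel, response,
              fixed = if (length(models[[i]])) models[[i]] else NULL,
              method = method, ...),
      error = function(e) NULL)
    if (is.null(f)) failed <- failed + 1L
    fits[[i]] <- f
  }
  if (failed > 0)
    warning(failed, " model(s) failed to fit and were excluded")
  fits
}

#' Rank fitted models by AICc
#'
#' @param fits list of `lmm_fit` objects (`NULL` entries, from failed fits,
#'   are excluded).
#' @return A data.frame with one row per converged model: `model`, `terms`,
#'   `k`, `aicc`, `delta` (AICc difference to the best model) and `weight`
#'   (Akaike weight, `exp(-delta/2)` normalized over the set).
#' @export
rank_models <- function(fits) {
  keep <- which(!vapply(fits, is.null, logical(1)))
  if (length(keep) == 0) stop_fluxtrend("no converged fits to rank")
  aiccs <- vapply(fits[keep], function(f) f$aicc, numeric(1))
  delta <- aiccs - min(aiccs)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  out <- data.frame(
    model = keep,
    terms = vapply(fits[keep], function(f)
      paste(f$fixed_terms %||% "1", collapse = " + "), character(1)),
    k = vapply(fits[keep], function(f) f$k_params, numeric(1)),
    aicc = aiccs, delta = delta, weight = w,
    stringsAsFactors = FALSE
  )
  out[order(out$delta), , drop = FALSE]
}

#' AICc multimodel averaging with zero substitution
#'
#' Retains every model within `delta_max` AICc units of the best model, refits
#' the retained set by REML, renormalizes the Akaike weights over it, and
#' averages each coefficient across the retained models with the estimate set
#' to zero where the term is absent (full-model averaging). The unconditional
#' standard error follows the revised Burnham-Anderson estimator
#' `sqrt(sum_m w_m (var_m + (b_m - b_bar)^2))`. A term's relative importance
#' is the summed weight of the retained models containing it.
#'
#' @param fits list of `lmm_fit` objects (ML fits used for ranking).
#' @param delta_max AICc window (default 4).
#' @param refit_reml refit retained models by REML before averaging?
#' @param conditional average only over models containing each term
#'   (subset/conditional averaging) instead of zero substitution.
#' @return An object of class `averaged_model`: `coefficients` (data.frame
#'   with `term`, `estimate`, `se`, `importance`, `z`, `p`), `retained`
#'   (ranking table of the retained set with renormalized weights),
#'   `fits` (the retained fits used for prediction), `delta_max`.
#' @export
average_model <- function(fits, delta_max = 4, refit_reml = TRUE,
                          conditional = FALSE) {
  ranking <- rank_models(fits)
  retained <- ranking[ranking$delta < delta_max, , drop = FALSE]
  rfits <- fits[retained$model]
  if (refit_reml) {
    rfits <- lapply(rfits, function(f)
      if (f$method == "REML") f else refit_lmm(f, "REML"))
  }
  w <- exp(-retained$delta / 2)
  w <- w / sum(w)
  retained$weight <- w

  all_terms <- unique(unlist(lapply(rfits, function(f) names(f$beta))))
  coefs <- lapply(all_terms, function(tm) {
    est <- vapply(rfits, function(f)
      if (tm %in% names(f$beta)) unname(f$beta[[tm]]) else 0, numeric(1))
    v <- vapply(rfits, function(f)
      if (tm %in% names(f$beta)) f$vcov[tm, tm] else 0, numeric(1))
    present <- vapply(rfits, function(f) tm %in% names(f$beta), logical(1))
    if (conditional && any(present)) {
      wc <- w[present] / sum(w[present])
      bbar <- sum(wc * est[present])
      se <- sqrt(sum(wc * (v[present] + (est[present] - bbar)^2)))
    } else {
      bbar <- sum(w * est)
      se <- sqrt(sum(w * (v + (est - bbar)^2)))
    }
    data.frame(term = tm, estimate = bbar, se = se,
               importance = sum(w[present]),
               z = if (se > 0) bbar / se else NA_real_,
               p = if (se > 0) 2 * pnorm(-abs(bbar / se)) else NA_real_,
               stringsAsFactors = FALSE)
  })
  coefs <- do.call(rbind, coefs)

  structure(list(coefficients = coefs, retained = retained, fits = rfits,
                 weights = w, delta_max = delta_max,
                 conditional = conditional,
                 response = rfits[[1]]$response,
                 group = rfits[[1]]$group, time = rfits[[1]]$time),
            class = "averaged_model")
}

#' @export
print.averaged_model <- function(x, ...) {
  cat(sprintf("Averaged model over %d retained model(s) (delta AICc < %g)\n",
              nrow(x$retained), x$delta_max))
  print(x$coefficients, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Predict from an averaged model
#'
#' The weight-averaged prediction of the retained models (linearity of
#' averaging: this equals the prediction under the averaged coefficients for
#' full-model averaging).
#'
#' @param object an `averaged_model`.
#' @param newdata data.frame of covariates.
#' @param include_random add site random effects (BLUPs) per retained model?
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.averaged_model <- function(object, newdata, include_random = FALSE, ...) {
  preds <- vapply(object$fits, function(f)
    predict_lmm(f, newdata, include_random = include_random)$fit,
    numeric(nrow(newdata)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
  as.numeric(preds %*% object$weights)
}

#' Does any retained model involve a given covariate?
#'
#' A covariate takes part in an averaged model when it appears as a main
#' effect or inside an interaction of at least one retained model.
#' @param avg an `averaged_model`.
#' @param covariate column name.
#' @return logical.
#' @export
covariate_in_model <- function(avg, covariate) {
  any(vapply(avg$fits, function(f) {
    any(covariate %in% unlist(strsplit(f$fixed_terms %||% character(),
                                       ":", fixed = TRUE)))
  }, logical(1)))
}
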