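test_that("the fit reduces to OLS without random terms or autocorrelation", {
  set.seed(1)
  p <- expand.grid(site = c("a", "b", "c"), year = 2001:2010)
  p$site <- as.character(p$site)
  p$x <- rnorm(nrow(p))
  p$y <- 1 + 2 * p$x + rnorm(nrow(p))
  fit <- fit_lmm(p, "y", fixed = "x", random = NULL, ar1 = FALSE,
                 method = "ML")
  ols <- coef(lm(y ~ x, p))
  expect_equal(unname(fit$beta), unname(ols), tolerance = 1e-6)
  expect_equal(fit$phi, 0)
  expect_equal(fit$var_intercept, 0)
  expect_equal(fit$var_slope, 0)
})

test_that("the single-site AR(1) log-likelihood matches a dense GLS oracle", {
  set.seed(2)
  years <- c(2001:2006, 2008:2012)  # gapped on purpose
  n <- length(years)
  y <- 0.4 * (years - 2006) + as.numeric(arima.sim(list(ar = 0.5), n))
  p <- data.frame(site = "a", year = years, y = y)
  fit <- fit_lmm(p, "y", fixed = ".time_c", random = NULL, ar1 = TRUE,
                 method = "ML")
  X <- cbind(1, years - mean(years))
  want <- oracle_ar1_loglik(y, X, unname(fit$beta), fit$sigma2, fit$phi, years)
  expect_equal(fit$loglik, as.numeric(want), tolerance = 1e-6)
})

test_that("the fitted likelihood is at least the likelihood at the truth", {
  set.seed(3)
  years <- 2001:2015
  y <- 1 + 0.3 * (years - mean(years)) +
    as.numeric(arima.sim(list(ar = 0.4), length(years), sd = 0.8))
  p <- data.frame(site = "a", year = years, y = y)
  fit <- fit_lmm(p, "y", fixed = ".time_c", random = NULL, ar1 = TRUE,
                 method = "ML")
  X <- cbind(1, years - mean(years))
  marg_sd_true <- 0.8 / sqrt(1 - 0.4^2)
  at_truth <- oracle_ar1_loglik(y, X, c(1, 0.3), marg_sd_true^2, 0.4, years)
  expect_gte(fit$loglik + 1e-8, as.numeric(at_truth))
})

test_that("fits are invariant to the order of fixed-effect terms", {
  p <- small_panel(seed = 4)
  f1 <- fit_lmm(p, "NEP_an", fixed = c("CO2_an", "Sdep_an", "MAT_an"),
                method = "ML")
  f2 <- fit_lmm(p, "NEP_an", fixed = c("MAT_an", "CO2_an", "Sdep_an"),
                method = "ML")
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
  expect_equal(f1$beta[sort(names(f1$beta))], f2$beta[sort(names(f2$beta))],
               tolerance = 1e-8)
  expect_equal(f1$aicc, f2$aicc, tolerance = 1e-8)
})

test_that("REML and ML agree on beta for a balanced single-group design", {
  set.seed(5)
  p <- data.frame(site = "a", year = 2001:2012)
  p$y <- 2 + 0.5 * p$year + rnorm(12)
  ml <- fit_lmm(p, "y", fixed = ".time_c", random = NULL, ar1 = FALSE,
                method = "ML")
  reml <- fit_lmm(p, "y", fixed = ".time_c", random = NULL, ar1 = FALSE,
                  method = "REML")
  expect_equal(ml$beta, reml$beta, tolerance = 1e-8)
})

test_that("the parameter count feeds the AICc as documented", {
  p <- small_panel(seed = 6)
  fit <- fit_lmm(p, "NEP_an", fixed = "CO2_an", method = "ML")
  # k = 2 fixed + 2 random variances + phi + sigma2
  expect_equal(fit$k_params, 6)
  expect_equal(aicc(fit),
               -2 * fit$loglik + 2 * 6 + 2 * 6 * 7 / (fit$n_obs - 7))
})

test_that("predictions are linear in the design and honour BLUPs", {
  p <- small_panel(seed = 7)
  fit <- fit_lmm(p, "NEP_an", fixed = c("CO2_an", "Sdep_an"), method = "ML")
  nd1 <- p[1:5, ]
  nd2 <- nd1
  nd2$CO2_an <- nd2$CO2_an + 1.5
  d <- predict_lmm(fit, nd2)$fit - predict_lmm(fit, nd1)$fit
  expect_equal(d, rep(1.5 * unname(fit$beta[["CO2_an"]]), 5))
  # unseen site: zero random part, flagged
  nd3 <- nd1
  nd3$site <- "ZZ"
  expect_warning(pr <- predict_lmm(fit, nd3, include_random = TRUE), "ZZ")
  expect_true(all(!pr$random_known))
  expect_equal(pr$fit, predict_lmm(fit, nd3, include_random = FALSE)$fit)
})

test_that("an intercept-only model without random terms predicts the mean", {
  set.seed(8)
  p <- data.frame(site = rep(c("a", "b"), each = 6), year = rep(2001:2006, 2),
                  y = rnorm(12))
  fit <- fit_lmm(p, "y", fixed = NULL, random = NULL, ar1 = FALSE,
                 method = "ML")
  pr <- predict_lmm(fit, p)
  expect_equal(pr$fit, rep(mean(p$y), 12), tolerance = 1e-8)
})

test_that("near-noise-free panels are reproduced through the site BLUPs", {
  # residual noise far smaller than the site offsets: the BLUPs must absorb
  # the offsets almost exactly and the fixed slope must be recovered
  p <- expand.grid(site = c("a", "b", "c", "d"), year = 2001:2012)
  p$site <- as.character(p$site)
  set.seed(9)
  p$x <- rnorm(nrow(p))
  site_off <- c(a = 3, b = -1, c = 0, d = 2)
  p$y <- site_off[p$site] + 2 * p$x + rnorm(nrow(p), 0, 1e-4)
  fit <- fit_lmm(p, "y", fixed = "x", method = "ML")
  expect_length(fit$notes, 0)  # the requested structure was kept
  pr <- predict_lmm(fit, p, include_random = TRUE)
  expect_lt(max(abs(pr$fit - p$y)), 1e-3)
  expect_equal(unname(fit$beta[["x"]]), 2, tolerance = 1e-4)
})

test_that("an impossible random structure downgrades with a note", {
  # two sites with two rows each cannot support intercept+slope+AR1;
  # the fit must still succeed through the fallback chain
  p <- data.frame(site = rep(c("a", "b"), each = 2),
                  year = rep(2001:2002, 2), y = c(1, 2, 1.5, 2.5))
  fit <- fit_lmm(p, "y", fixed = NULL, random = c("intercept", "slope"),
                 ar1 = TRUE, method = "ML")
  expect_s3_class(fit, "lmm_fit")
  expect_true(fit$converged)
})

test_that("the fixed-structure GLS trend matches the paper conventions", {
  # noise-free common slope: recovered exactly under any structure
  p <- expand.grid(site = c("a", "b", "c"), year = 2001:2012)
  p$site <- as.character(p$site)
  p$y <- 1.7 * (p$year - 2006) + ifelse(p$site == "a", 4, -2)
  struct <- list(var_intercept = 2, var_slope = 0.5, phi = 0.3, sigma2 = 1,
                 time_center = 2006.5)
  tr <- fluxtrend:::gls_trend(p$year, p$site, p$y, struct)
  expect_equal(tr$slope, 1.7, tolerance = 1e-10)
  # linearity: L(a x + b z) = a L(x) + b L(z)
  set.seed(10)
  x <- rnorm(nrow(p))
  z <- rnorm(nrow(p))
  lx <- fluxtrend:::gls_trend(p$year, p$site, x, struct)$slope
  lz <- fluxtrend:::gls_trend(p$year, p$site, z, struct)$slope
  lcomb <- fluxtrend:::gls_trend(p$year, p$site, 2 * x - 3 * z, struct)$slope
  expect_equal(lcomb, 2 * lx - 3 * lz, tolerance = 1e-10)
  # per-site constant shifts carry exactly zero trend
  shift <- ifelse(p$site == "a", 100, ifelse(p$site == "b", -40, 7))
  lshift <- fluxtrend:::gls_trend(p$year, p$site, x + shift, struct)$slope
  expect_equal(lshift, lx, tolerance = 1e-9)
})
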