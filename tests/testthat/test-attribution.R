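# noise-free helper: NEP responds only to CO2 (beta 4.8) and the CO2 ramp is
# exact, so the CO2 contribution is 4.8 * 2.0 = 9.6 in closed form
noise_free_panel <- function(seed = 5, n_sites = 6) {
  zero <- c(NEP = 0, GPP = 0, Re = 0, LAI = 0)
  simulate_panel(sim_config(
    n_sites = n_sites, seed = seed, co2_sd = 0, sdep_sd = 0, ndep_sd = 0,
    mat_sd = 0.5, map_cv = 0, spei_sd = 1,
    true_beta = list(
      NEP = c(CO2 = 4.8, Sdep = 0, Ndep = 0, MAT = 0, SPEI = 0, LAI = 0),
      GPP = c(CO2 = 0, Sdep = 0, Ndep = 0, MAT = 0, SPEI = 0, LAI = 0),
      Re = c(CO2 = 0, Sdep = 0, Ndep = 0, MAT = 0, SPEI = 0, LAI = 0),
      LAI = c(CO2 = 0, Sdep = 0, Ndep = 0, MAT = 0, SPEI = 0)
    ),
    random_intercept_sd = zero, random_slope_sd = zero, resid_sd = zero))
}

test_that("a pure CO2 model yields the closed-form contribution 9.6", {
  p <- noise_free_panel()
  fit <- fit_lmm(p, "NEP_an", fixed = "CO2_an", method = "ML")
  avg <- average_model(list(fit))
  rec <- contribution(avg, p, "CO2_an")
  expect_true(rec$in_model)
  expect_equal(rec$contribution, 9.6, tolerance = 1e-6)
})

test_that("drivers absent from every retained model contribute exactly zero", {
  p <- noise_free_panel()
  fit <- fit_lmm(p, "NEP_an", fixed = "CO2_an", method = "ML")
  avg <- average_model(list(fit))
  rec <- contribution(avg, p, "MAT_an")
  expect_false(rec$in_model)
  expect_identical(rec$contribution, 0)
  expect_identical(rec$contribution_se, 0)
})

test_that("holding a constant driver at its site medians changes nothing", {
  p <- noise_free_panel()
  p$flat <- ifelse(p$site == unique(p$site)[1], 5, 7)  # constant per site
  fit <- fit_lmm(p, "NEP_an", fixed = c("CO2_an", "flat"), method = "ML")
  avg <- average_model(list(fit))
  rec <- contribution(avg, p, "flat")
  expect_equal(rec$contribution, 0, tolerance = 1e-10)
})

test_that("the decomposition identity holds to machine precision", {
  p <- small_panel(seed = 17)
  fit <- fit_lmm(p, "NEP_an", fixed = c("CO2_an", "Sdep_an", "MAT_an"),
                 method = "ML")
  avg <- average_model(list(fit))
  dec <- decompose_trend(avg, p, c("CO2_an", "Sdep_an", "MAT_an"))
  expect_equal(dec$observed_trend,
               sum(dec$contributions$contribution) + dec$unknown,
               tolerance = 1e-12)
})

test_that("the unknown term vanishes on noise-free linear panels", {
  p <- noise_free_panel()
  fit <- fit_lmm(p, "NEP_an",
                 fixed = c("CO2_an", "Sdep_an", "Ndep_an", "MAT_an", "SPEI"),
                 method = "ML")
  avg <- average_model(list(fit))
  dec <- decompose_trend(avg, p,
                         c("CO2_an", "Sdep_an", "Ndep_an", "MAT_an", "SPEI"))
  expect_lt(abs(dec$unknown), 1e-8)
  expect_equal(dec$observed_trend, dec$model_trend, tolerance = 1e-8)
})

test_that("with no drivers the unknown equals the observed trend", {
  p <- small_panel(seed = 18)
  fit <- fit_lmm(p, "NEP_an", fixed = "CO2_an", method = "ML")
  avg <- average_model(list(fit))
  dec <- decompose_trend(avg, p, character(0))
  expect_equal(dec$unknown, dec$observed_trend)
  expect_equal(nrow(dec$contributions), 0)
})

test_that("contributions do not depend on the order drivers are held", {
  p <- small_panel(seed = 19)
  fit <- fit_lmm(p, "NEP_an", fixed = c("CO2_an", "Sdep_an", "MAT_an"),
                 method = "ML")
  avg <- average_model(list(fit))
  d1 <- decompose_trend(avg, p, c("CO2_an", "Sdep_an", "MAT_an"))
  d2 <- decompose_trend(avg, p, c("MAT_an", "CO2_an", "Sdep_an"))
  c1 <- setNames(d1$contributions$contribution, d1$contributions$driver)
  c2 <- setNames(d2$contributions$contribution, d2$contributions$driver)
  expect_equal(c1[sort(names(c1))], c2[sort(names(c2))], tolerance = 1e-12)
  expect_equal(d1$unknown, d2$unknown, tolerance = 1e-12)
})

test_that("sensitivities follow the quotient rule", {
  contr <- list(driver = "X", contribution = 10, contribution_se = 2)
  dt <- list(slope = 2, slope_se = 0.2)
  s <- sensitivity(contr, dt)
  expect_equal(s$sensitivity, 5)
  expect_equal(s$sensitivity_se, 5 * sqrt((2 / 10)^2 + (0.2 / 2)^2))
  expect_equal(round(s$sensitivity_se, 3), 1.118)
})

test_that("exact inputs give an exact sensitivity and zero error", {
  s <- sensitivity(list(driver = "CO2", contribution = 9.6,
                        contribution_se = 0),
                   list(slope = 2.0, slope_se = 0))
  expect_equal(s$sensitivity, 4.8)
  expect_equal(s$sensitivity_se, 0)
  expect_equal(s$p_value, 0)
})

test_that("sensitivity scales and degenerates as documented", {
  base <- sensitivity(list(driver = "X", contribution = 10,
                           contribution_se = 2),
                      list(slope = 2, slope_se = 0.2))
  dbl <- sensitivity(list(driver = "X", contribution = 20,
                          contribution_se = 4),
                     list(slope = 2, slope_se = 0.2))
  expect_equal(dbl$sensitivity, 2 * base$sensitivity)
  expect_equal(dbl$sensitivity_se, 2 * base$sensitivity_se)
  zero <- sensitivity(list(driver = "X", contribution = 0,
                           contribution_se = 3),
                      list(slope = 2, slope_se = 0.2))
  expect_equal(zero$sensitivity, 0)
  expect_equal(zero$sensitivity_se, 1.5)
  expect_error(sensitivity(list(driver = "X", contribution = 1,
                                contribution_se = 1),
                           list(slope = 0, slope_se = 1)),
               "driver trend is zero")
})

test_that("offset ratios report percentages with propagated errors", {
  exact <- offset_ratio(list(contribution = -2, contribution_se = 0),
                        list(contribution = 10, contribution_se = 0))
  expect_equal(exact$percent, 20)
  expect_equal(exact$percent_se, 0)
  noisy <- offset_ratio(list(contribution = -2, contribution_se = 1),
                        list(contribution = 10, contribution_se = 2))
  expect_equal(noisy$percent, 20)
  expect_equal(round(noisy$percent_se, 2), 10.77)
  zero <- offset_ratio(list(contribution = 0, contribution_se = 1),
                       list(contribution = 10, contribution_se = 2))
  expect_equal(zero$percent, 0)
  expect_equal(zero$percent_se, 10)
  expect_error(offset_ratio(list(contribution = 1, contribution_se = 1),
                            list(contribution = 0, contribution_se = 1)),
               "reference contribution is zero")
})

test_that("recovered contributions agree with the stored ground truth", {
  # contributions are unbiased, but the propagated SE conditions on the
  # estimated variance components and so runs modestly anti-conservative on a
  # short panel; test calibration in the mean over panels, not on one draw
  zs <- vapply(1:8, function(s) {
    p <- small_panel(seed = s, n_sites = 12)
    fit <- fit_lmm(p, "NEP_an", fixed = c("CO2_an", "Sdep_an", "Ndep_an"),
                   method = "ML")
    avg <- average_model(list(fit))
    dec <- decompose_trend(avg, p, c("CO2_an", "Sdep_an"))
    gt <- attr(p, "ground_truth")$NEP
    ctab <- dec$contributions
    vapply(c("CO2", "Sdep"), function(d) {
      got <- ctab[ctab$driver == paste0(d, "_an"), ]
      (got$contribution - gt$contribution[gt$driver == d]) / got$se
    }, numeric(1))
  }, numeric(2))
  # no single panel wildly off, and no systematic bias across panels
  expect_lt(max(abs(zs)), 5)
  expect_lt(abs(mean(zs["CO2", ])), 1.5)
  expect_lt(abs(mean(zs["Sdep", ])), 1.5)
})
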