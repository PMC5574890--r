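test_that("panels round-trip through write and read at full precision", {
  p <- small_panel(seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel(p, path)
  q <- read_panel(path)
  expect_equal(nrow(q), nrow(p))
  expect_equal(q$NEP, p$NEP)
  expect_equal(q$CO2_an, p$CO2_an)
  expect_identical(q$site, p$site)
  expect_identical(q$year, as.integer(p$year))
})

test_that("duplicate site-year rows are rejected naming the offenders", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,year,NEP", "a,2001,1", "a,2001,2", "b,2002,3"), path)
  expect_error(read_panel(path), "a/2001")
})

test_that("missing required columns and fractional years are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,year,NEP", "a,2001,1"), path)
  expect_error(read_panel(path, required = "GPP"), "GPP")
  writeLines(c("site,year,NEP", "a,2001.5,1"), path)
  expect_error(read_panel(path), "non-integral")
})

test_that("anomalies are annual value minus site mean", {
  p <- data.frame(site = "a", year = 1:3, x = c(10, 12, 14))
  a <- compute_anomalies(p, "x")
  expect_equal(a$x_c, rep(12, 3))
  expect_equal(a$x_an, c(-2, 0, 2))
})

test_that("anomalies sum to zero per site and respect missing cells", {
  p <- small_panel(seed = 5)
  sums <- tapply(p$MAT_an, p$site, sum)
  expect_true(all(abs(sums) < 1e-9))
  # a missing cell stays missing; the site mean uses observed years only
  q <- data.frame(site = c("a", "a", "a", "b", "b"), year = c(1, 2, 3, 1, 2),
                  x = c(1, NA, 3, NA, NA))
  a <- compute_anomalies(q, "x")
  expect_equal(a$x_c[1:3], rep(2, 3))
  expect_equal(a$x_an, c(-1, NA, 1, NA, NA))
  expect_true(all(is.na(a$x_c[4:5])))
})

test_that("plausible monotone CO2 series pass QC untouched", {
  res <- qc_fill_co2(1:3, c(370, 372, 374))
  expect_true(all(res$flag == "ok"))
  expect_equal(res$co2, c(370, 372, 374))
})

test_that("a dip below its predecessor is flagged and refilled between its neighbours", {
  res <- qc_fill_co2(1:5, c(368, 370, 365, 374, 376))
  expect_equal(res$flag[3], "filled")
  expect_gt(res$co2[3], 370)
  expect_lt(res$co2[3], 374)
  expect_equal(res$original[3], 365)
  expect_true(all(res$flag[-3] == "ok"))
})

test_that("a jump much larger than the normal 2 ppm increase is flagged", {
  res <- qc_fill_co2(1:5, c(368, 370, 372, 390, 376))
  expect_equal(res$flag[4], "filled")
  expect_true(all(res$flag[-4] == "ok"))
  expect_lt(res$co2[4], 390)
})

test_that("QC is idempotent on its own output", {
  res <- qc_fill_co2(1:6, c(368, 370, 365, 374, 390, 378))
  res2 <- qc_fill_co2(res$year, res$co2)
  expect_true(all(res2$flag == "ok"))
  expect_equal(res2$co2, res$co2)
})

test_that("too few plausible values fall back to the reference or stay missing", {
  years <- 1:4
  bad <- c(380, 360, 385, 350)  # pervasive violations: < min_points retained
  ref <- data.frame(year = 1:4, CO2 = c(370, 372, 374, 376))
  res <- qc_fill_co2(years, bad, reference = ref)
  expect_true(any(res$flag == "reference"))
  expect_equal(res$co2[res$flag == "reference"],
               ref$CO2[match(res$year[res$flag == "reference"], ref$year)])
  expect_warning(res2 <- qc_fill_co2(years, bad), "unfilled")
  expect_true(any(res2$flag == "unfilled"))
  expect_true(all(is.na(res2$co2[res2$flag == "unfilled"])))
})

test_that("corrected maturity age is the stand-age to maturity-age quotient", {
  expect_equal(round(corrected_maturity_age(80, 90), 2), 0.89)
  expect_equal(round(corrected_maturity_age(118, 95), 2), 1.24)
  expect_equal(corrected_maturity_age(75, 75), 1)
  expect_error(corrected_maturity_age(0, 90), "positive")
  expect_error(corrected_maturity_age(80, -1), "positive")
})

test_that("cumulative deposition sums the preceding window strictly", {
  p <- data.frame(site = "a", year = 1:6, Ndep = c(1, 2, 3, 4, 5, 6))
  out <- cumulative_deposition(p, "Ndep", window = 5)
  expect_equal(out$Ndep_cum5[6], 15)
  expect_true(all(is.na(out$Ndep_cum5[1:5])))
  q <- data.frame(site = "a", year = 1:6, Ndep = rep(1, 6))
  expect_equal(cumulative_deposition(q, "Ndep", 5)$Ndep_cum5[6], 5)
})

test_that("lenient cumulative deposition sums what is available", {
  p <- data.frame(site = "a", year = c(1, 2, 4, 5, 6), Ndep = c(1, 2, 4, 5, 6))
  strict <- cumulative_deposition(p, "Ndep", window = 5, mode = "strict")
  lenient <- cumulative_deposition(p, "Ndep", window = 5, mode = "lenient")
  expect_true(is.na(strict$Ndep_cum5[5]))     # year 3 missing from window
  expect_equal(lenient$Ndep_cum5[5], 1 + 2 + 4 + 5)
})

test_that("strict cumulative deposition matches brute force on random panels", {
  set.seed(8)
  p <- data.frame(site = rep(c("a", "b"), each = 8),
                  year = c(2001:2008, 2003:2010),
                  Sdep = runif(16, 1, 3))
  out <- cumulative_deposition(p, "Sdep", window = 3)
  for (i in seq_len(nrow(p))) {
    want <- (p$year[i] - 3):(p$year[i] - 1)
    rows <- p$site == p$site[i] & p$year %in% want
    expected <- if (sum(rows) == 3) sum(p$Sdep[rows]) else NA_real_
    expect_equal(out$Sdep_cum3[i], expected)
  }
})

test_that("warm-season aggregation covers April through September", {
  m <- expand.grid(year = 2001, month = 1:12)
  m$MAT <- 10
  m$MAP <- 100
  m$SPEI <- 0.5
  out <- warm_season_aggregate(m)
  expect_equal(out$MAT_warm, 10)
  expect_equal(out$MAP_warm, 600)
  expect_equal(out$SPEI_warm, 0.5)
  m2 <- expand.grid(year = 2001, month = 1:12)
  m2$MAT <- m2$month
  expect_equal(warm_season_aggregate(m2)$MAT_warm, mean(4:9))
})

test_that("missing warm-season months yield missing values unless allowed", {
  m <- expand.grid(year = 2001, month = c(1:3, 4:7, 10:12))  # Aug, Sep absent
  m$MAT <- 10
  expect_true(is.na(warm_season_aggregate(m)$MAT_warm))
  expect_equal(warm_season_aggregate(m, min_frac = 0.5)$MAT_warm, 10)
})
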