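#' Published per-site trend table of the 23-forest network
#'
#' Returns the packaged summary table of the 23 temperate and boreal forests:
#' site characteristics (climate class, forest type, stand age, logging
#' maturity age and the corrected maturity age = stand age / maturity age,
#' measurement window and number of years) together with the published
#' Theil-Sen trends, their standard errors and one-tailed P values
#' (H1: trend > 0) for annual NEP, GPP, Re (g C m^-2 yr^-2) and maximum LAI
#' (m^2 m^-2 yr^-1). The LAI trend is missing (not zero) for Vielsalm. A
#' reported P of "<0.0001" is stored as 0.0001.
#'
#' @return A data.frame with 23 rows.
#' @examples
#' t1 <- table1_trends()
#' trend_sign_summary(data.frame(slope = t1$nep_trend,
#'                               p_one_tailed = t1$nep_p))
#' @export
table1_trends <- function() {
  path <- system.file("extdata", "table1_trends.csv", package = "fluxtrend",
                      mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
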