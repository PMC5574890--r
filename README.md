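# fluxtrend

Trend estimation and driver attribution for multi-site forest carbon-flux
panels.

Eddy-covariance networks measure annual net ecosystem production (NEP), gross
primary production (GPP) and ecosystem respiration (Re) at forest sites over
one or two decades, alongside canopy leaf area index (LAI) and environmental
drivers: atmospheric CO₂, sulphur and nitrogen deposition, temperature and
water availability. Two questions drive the analysis this package implements:

1. **Are the fluxes trending?** Per-site robust trends (Theil–Sen slopes with
   one-tailed Mann–Kendall tests, exact for short untied series), a bootstrap
   test of whether the cross-site trend-sign distribution could be chance, and
   the panel mean trend from a linear mixed model with site-level random
   intercepts and slopes and AR(1) residual autocorrelation (gap-aware,
   `phi^|Δyear|`).
2. **What drives the trends?** All admissible submodels of a saturated
   anomaly/interaction specification are enumerated under marginality, ranked
   by AICc, and averaged with zero substitution (full-model averaging with
   revised unconditional standard errors). The averaged model then yields
   counterfactual attributions: each driver's temporal contribution is the
   trend of the model predictions minus the trend of the predictions with
   that driver held at its site median, both evaluated with one fixed
   mixed-model covariance structure so the decomposition
   `observed = Σ contributions + unknown` is exact by construction.
   Contributions divided by the driver's own trend give sensitivities
   (response units per driver unit). Across-site variation in trends is
   explained by weighted forward selection with a PMVD (proportional marginal
   variance decomposition) relative-importance breakdown.

A synthetic panel generator with stored ground truth (known sensitivities,
shared rising CO₂, geometrically declining deposition, AR(1) noise, site
random effects) supports end-to-end verification: `recovery_study()` checks
that the attributed CO₂ sensitivity is unbiased with calibrated intervals.

## Worked example

Simulate a 12-site panel whose NEP responds to CO₂ (sensitivity 4.8 per ppm)
and sulphur deposition (24 per kg S ha⁻¹ yr⁻¹), then recover those facts.

```r
library(fluxtrend)

panel <- simulate_panel(sim_config(n_sites = 12, seed = 1))
head(panel[, c("site", "year", "CO2", "Sdep", "Ndep", "MAT", "NEP", "NEP_an")])
#>   site year   CO2  Sdep  Ndep   MAT   NEP  NEP_an
#> 1  S01 1998 368.2 1.281 4.338 5.484 285.4  52.567
#> 2  S01 1999 370.4 1.215 4.754 6.314 285.3  52.452
#> 3  S01 2000 372.3 1.148 4.589 6.245 230.4  -2.482
#> 4  S01 2001 373.8 1.093 4.319 5.956 275.4  42.596
#> 5  S01 2002 376.8 1.055 4.228 7.030 229.2  -3.666
#> 6  S01 2003 378.2 0.962 4.183 6.532 162.4 -70.480
```

Per-site robust trends are noisy at 13 annual values per site — single sites
can even trend the wrong way — which is why the cross-site view matters:

```r
s1 <- panel[panel$site == "S01", ]
theil_sen(s1$year, s1$NEP)
#> Trend (theil_sen): -4.411 +/- 3.292 per year, one-tailed P = 0.9616 (n = 13)

slopes <- sapply(split(panel, panel$site),
                 function(d) theil_sen(d$year, d$NEP)$slope)
bootstrap_sign_test(slopes, B = 10000, seed = 2)$boot_p
#> [1] 2e-04        # 11 of 12 sites trend upward; chance is rejected
```

The panel mean trend pools all sites in one mixed model (random intercepts
and slopes per site, AR(1) residuals). The generator's ground truth for this
panel is a mean NEP trend of 7.9 g C m⁻² yr⁻² (9.7 from CO₂, −1.8 from
declining S deposition):

```r
mean_trend_lmm(panel, "NEP_an")
#> Trend (lmm): 9.241 +/- 1.976 per year, one-tailed P = 1.465e-06 (n = 201)
```

Enumerate and average all 16 admissible models over four anomaly terms, then
decompose the observed trend:

```r
terms <- c("CO2_an", "Sdep_an", "Ndep_an", "MAT_an")
fits <- fit_model_set(panel, "NEP_an", enumerate_models(terms))
avg <- average_model(fits)
avg
#> Averaged model over 7 retained model(s) (delta AICc < 4)
#>         term estimate      se importance        z         p
#>  (Intercept)    2.904  4.1437     1.0000  0.70075 4.835e-01
#>       CO2_an    5.082  0.9885     1.0000  5.14111 2.731e-07
#>       MAT_an   -4.738  5.3718     0.5951 -0.88193 3.778e-01
#>      Ndep_an   -1.942  5.8365     0.2858 -0.33265 7.394e-01
#>      Sdep_an   -0.511 14.0734     0.2294 -0.03631 9.710e-01

dec <- decompose_trend(avg, panel, terms)
dec
#> Observed trend: 9.881 +/- 1.988; model trend: 10.12 +/- 1.988
#>   driver contribution      se   p_value in_model
#>   CO2_an     10.23487 1.93878 1.299e-07     TRUE
#>  Sdep_an      0.03817 0.53262 9.429e-01     TRUE
#>  Ndep_an      0.14083 0.31778 6.576e-01     TRUE
#>   MAT_an     -0.03126 0.03529 3.757e-01     TRUE
#> Unknown remainder: -0.5019 +/- 2.846
```

The CO₂ contribution (10.2 ± 1.9) covers its ground truth (9.65), and
dividing by the CO₂ trend recovers the configured sensitivity:

```r
sensitivity(dec$records[[1]], mean_trend_lmm(panel, "CO2_an"))
#> Sensitivity to CO2_an: 5.091 +/- 0.9646 per driver unit (one-sided P = 6.521e-08)
# truth: 4.8
```

Over 200 replicate panels `recovery_study()` confirms the estimator is
unbiased (mean 4.80, Monte-Carlo SE 0.07) with 93% coverage of nominal 95%
intervals.

The bundled 23-site network trend table (`table1_trends()`) and the one-shot
driver `run_pipeline()` tie these stages together; see the vignette
(`vignettes/flux-trend-attribution.Rmd`) for the methods in detail.

## Reproduction

Everything is deterministic given a seed.

```sh
# unit + acceptance tests (~1 minute) against the installed package
Rscript -e 'testthat::test_dir("tests/testthat", package = "fluxtrend",
                               load_package = "installed")'

# end-to-end acceptance run (~1 minute), writes headline quantities as JSON
Rscript scripts/acceptance.R --seed 42 --out acceptance.json
```

The acceptance script reports, among other quantities: the published-network
sign summaries (18 of 23 sites with increasing NEP, 11 significant), exact
bootstrap tail probabilities against enumeration, the additivity gap of the
attribution (zero to machine precision), and the 200-panel CO₂-sensitivity
recovery (mean within 2 Monte-Carlo SEs of 4.8, ≥ 90% coverage).
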