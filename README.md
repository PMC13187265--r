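# dendrodrought

Dual-proxy tree-ring reconstruction of atmospheric and soil drought, for
dendroclimatologists working in semi-arid mountain forests where ring width
(TRW) and ring-cellulose δ¹⁸O carry complementary drought signals.

Trees experience *soil drought* (accumulated water-balance deficits, indexed
by SPEI-type standardized indices) and *atmospheric drought* (high vapor
pressure deficit, VPD) as distinct stresses.  TRW mainly records the former;
δ¹⁸O records leaf-water evaporative enrichment and hence the latter.  This
package implements the full workflow that separates the two over a
multi-century common period:

1. **Chronologies** — signal-free detrending of ring-width series (growth
   curve fit ↔ biweight-mean chronology iterated to convergence), with the
   classical quality statistics: rbar, EPS = n·r̄/(1+(n−1)·r̄),
   SNR = n·r̄/(1−r̄), per-year SSS, AC1, and Gleichläufigkeit.
2. **Isotope elevation normalization** — OLS of per-tree mean δ¹⁸O on
   elevation, δ¹⁸O_corr = δ¹⁸O_obs + β₁·(ref − elevation), then a mean
   isotope chronology with a t-based 95% band and a replication rule.
3. **Climate indices** — Magnus-form VPD = es(T)·(1 − RH/100); a
   standardized k-month moisture index from the Thornthwaite water balance
   (empirical normal-score standardization).
4. **Calibration & validation** — bootstrapped Spearman screening grids;
   OLS transfer functions (δ¹⁸O → VPD; δ¹⁸O + RWI → moisture index) with
   R², adjusted R², residual SE, Durbin–Watson, VIF; leave-one-out
   cross-validation with RMSE, MAE, R²cv and reduction of error
   RE = 1 − SSE(pred)/SSE(climatology).
5. **Reconstruction** — transfer applied over the full proxy period with a
   ±1 residual-SE band and a 10-year FFT low-pass view.
6. **Drought typology** — k-means (k = 3) on reconstructed VPD, moisture
   index, and their combined z-scored matrix, labelled severe/moderate/
   non-drought by a fixed severity ordering; cluster summaries, combined-
   cluster composition, and 50-year severity trends.
7. **Growth response** — superposed epoch analysis around severe years with
   a 1000-draw Monte-Carlo null and percentile confidence bands.

A seeded synthetic-data module (`synthetic_config()`, `generate_climate()`,
`generate_proxies()`) produces multi-tree proxy networks with known transfer
functions and exposes the ground truth, so every stage is testable without
any external data.  See the methods vignette
(`vignettes/dual-proxy-drought.Rmd`) for the model account and design
decisions.

## Worked example

```r
library(dendrodrought)

res <- run_pipeline(pipeline_config(), out_dir = "drought_run")

res$trw$stats
#>   rbar = 0.316  EPS = 0.977  SNR = 42.511  AC1 = 0.021  (n_eff = 91.8, 4371 pairs)

res$calibration$vpd_model
#> Transfer model: target = -1.509 +0.128*d18o
#>   n = 37 (1984-2020)  R2 = 0.616  adj R2 = 0.605  rse = 0.164  DW = 2.11
#>   VIF: d18o=1.000   Shapiro-Wilk p = 0.855

res$calibration$vpd_cv
#> LOOCV: RMSE = 0.168  MAE = 0.128  R2cv = 0.577  RE = 0.576  (n = 37, 0 fold(s) skipped)
#>   RE null model: calibration-period mean (classical dendro RE)

subset(res$typology$summary, scheme == "COMB",
       c(label, n_years, mean_spei, mean_vpd, mean_rwi))
#>  label n_years  mean_spei mean_vpd  mean_rwi
#>      D      46 -1.0564448 3.203258 0.8977039
#>      M      85 -0.1055596 2.953517 0.9659460
#>     ND      69  0.8533765 2.734524 1.1101480

res$sea$comparison
#>  scheme n_events lag0_anomaly lag0_significant recovery_lag
#>    SPEI       56   -0.7233714             TRUE            1
#>     VPD       41    0.2154673            FALSE            1
#>    COMB       45   -0.2824292            FALSE            1
```

Reading the output: the ring-width chronology has a strong common signal
(EPS 0.977 at ~92 cores).  Elevation-corrected δ¹⁸O explains 62% of the
variance in the simulated March–September VPD over the 37-year calibration
window, and leave-one-out validation retains that skill (RE 0.58 against
the climatological mean — positive RE means the model beats climatology).
Of the 200 reconstructed years, 65.5% classify as combined drought years
(severe + moderate); growth drops significantly in soil-drought years
(lag-0 anomaly −0.72 standardized units) but not in atmospheric-drought
years, with recovery by lag +1.  Every run writes its intermediate tables
and a manifest (seeds, switches, checksums) into `out_dir`.

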