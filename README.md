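# lipoflux

Quantitative analysis of pulse-chase lipid trafficking experiments with
bifunctional lipid probes. After a defined pool of a single lipid species is
loaded into the plasma membrane (PM), its redistribution across organelles
(endosomes, Golgi, ER, mitochondria) is followed by fluorescence imaging,
and its metabolic fate by species-resolved shotgun lipidomics. lipoflux
provides the computational layer for both readouts, for cell biologists and
lipid biochemists running such experiments:

* **Signal partitioning** — assign the lipid fluorescence channel to
  organelles from classifier probability maps; where organelle masks
  overlap, split each pixel's intensity by the likelihood of its intensity
  under per-organelle distributions learned from unambiguous pixels.
* **Compartmental kinetics** — a family of linear compartment models
  `dx/dt = A(k) x` of retrograde (PM → organelles) and anterograde
  (ER → PM) lipid transport, solved exactly; global bounded least-squares
  fitting of all rate constants (min⁻¹) with multi-start
  Levenberg–Marquardt; 100-run Monte Carlo uncertainty; condition
  comparison by fold change and Cohen's *d*. Derived quantities: the
  quasi-equilibrium constant `K = k_PM_ER / k_ER_PM` and the non-vesicular
  share `k_PM_ER / (k_PM_ER + k_PM_Endo)` of retrograde flux.
* **Metabolism from MS** — exact-mass discrimination of probe-derived from
  native species (the diazirine N₂ vs 2×CH₂ doublet, 28.0061 vs
  28.0313 Da), supplied-species and total-bifunctional fractions over time,
  mono-exponential turnover fits (`k_met`), and the transport/metabolism
  rate ratio with error propagation.
* **Synthetic data** — generators for time courses, toy organelle images
  and MS species tables with known ground truth, so every stage is testable
  end to end without downloads.

## Worked example

Simulate a PM ⇄ ER exchange experiment at the wild-type PE regime
(`k_PM_ER` = 0.22, `k_ER_PM` = 0.10 min⁻¹), refit it, and quantify
uncertainty:

```r
library(lipoflux)

model <- flux_model("pm_er")
tc  <- sim_timecourse(model, c(k_PM_ER = 0.22, k_ER_PM = 0.10),
                      noise_sd = 0.02, seed = 1)
fit <- fit_flux(tc, model, x0 = c(PM = 1, ER = 0), seed = 1)
fit <- mc_uncertainty(fit, n_mc = 100, seed = 2)
tidy(fit)
#> # A tibble: 2 × 6
#>   term    estimate mc_mean   mc_sd     cv poorly_identified
#>   <chr>      <dbl>   <dbl>   <dbl>  <dbl> <lgl>
#> 1 k_PM_ER   0.219    0.220 0.0102  0.0461 FALSE
#> 2 k_ER_PM   0.0999   0.100 0.00604 0.0602 FALSE
```

Both generating rates are recovered within ~1%, with Monte Carlo s.d.
about 5% of the estimate. The steady-state partitioning between PM and ER:

```r
quasi_equilibrium(fit)
#> # A tibble: 1 × 3
#>       K mc_mean  mc_sd
#>   <dbl>   <dbl>  <dbl>
#> 1  2.20    2.20 0.0778
```

`K ≈ 2.2` means the lipid is about twice as likely to sit in the PM as in
the ER at steady state. Metabolism is then quantified from a synthetic MS
table and compared with transport:

```r
tab  <- sim_ms_table(k_met = 0.005, seed = 3)
mfit <- fit_monoexponential(fraction_supplied(tab))
mfit
#> <metabolism_fit> mono-exponential
#>   k_met = 0.005135 min^-1  (s.e. 7.64e-05 ),  f0 = 1

transport_metabolism_ratio(fit, mfit)
#> # A tibble: 1 × 3
#>   ratio    sd infinite
#>   <dbl> <dbl> <lgl>
#> 1  42.9  2.08 FALSE
```

Transport is ~43-fold faster than metabolic conversion here — inside the
order-of-magnitude separation typical of these probes. `plot_timecourse()`,
`autoplot()` and `plot_mc_rates()` visualize data, fits and MC
distributions; `run_pipeline(pipeline_config(...))` chains all stages and
writes fit JSON, fraction CSVs and a summary.

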