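# ninflux

Biphasic Michaelis–Menten analysis of short-term ¹⁵N tracer influx into
plant roots, with simulators and tidy metabolite analytics.

## The problem

Root uptake of ammonium and nitrate is carried by two transport systems: a
high-affinity system (HATS) that saturates at low external concentration,
and a low-affinity system (LATS) that contributes only once the external
concentration is high enough. Influx assays measure the uptake rate *v*
(μmol g⁻¹ DW h⁻¹) of ¹⁵N-labelled substrate across a concentration grid
(typically 0.01–10 mM, a few replicate plants per concentration), and the
biology is summarised by five constants: `V1`, `Km1` (HATS), `V2`, `Km2`
(LATS) and the LATS activation threshold `T`. `ninflux` is for researchers
who run or reanalyse such assays and want the fitting, model comparison,
uncertainty and simulation machinery in one tested package.

The core rate law is a two-stage Michaelis–Menten curve, continuous at the
threshold:

```
v(S) = V1·S/(Km1 + S)                                    S <  T
v(S) = V1·T/(Km1 + T) + V2·(S − T)/(Km2 + S − T)         S >= T
```

It is fitted to replicate-level records by profiled nonlinear least
squares: the threshold `T` is profiled over a finite candidate set (the
observed concentrations plus their midpoints), and for each fixed `T` the
remaining parameters are estimated by variable projection (`V1`, `V2`
solved linearly; bounded search over `log Km1`, `log Km2` initialised from
a Hanes–Woolf linearisation). The single-phase model is fitted the same
way for AICc-based model comparison, and uncertainty comes from a
case-resampling bootstrap stratified within concentration levels. See the
vignette in `vignettes/biphasic-influx-kinetics.Rmd` for the full account
of the method and its numerical choices.

## Worked example

Simulate a nitrate influx assay (13 concentrations × 4 replicates,
multiplicative noise, CV 5%) from published-style constants, refit it, and
ask whether the biphasic model is warranted:

```r
library(ninflux)

nitrate <- kinetic_params(V1 = 2.02, Km1 = 0.31, V2 = 16.0, Km2 = 2.29, T = 2)
assay <- simulate_influx(nitrate, assay_design("nitrate"),
                         noise_model(cv_or_sigma = 0.05), seed = 42)
fit <- fit_two_stage(assay)
fit <- bootstrap_ci(assay, fit, n_boot = 200, seed = 42)
fit
#> Two-stage Michaelis-Menten fit: n = 52, SSE = 2.1965, converged: TRUE
#> Two-stage Michaelis-Menten parameters
#>   high-affinity: V1 = 1.9891 umol/g DW/h, Km1 = 0.309072 mM
#>   low-affinity:  V2 = 15.9852 umol/g DW/h, Km2 = 2.29379 mM
#>   activation threshold T = 2 mM
#> bootstrap 95% percentile intervals (200 resamples):
#>  term   conf.low  conf.high
#>    V1  1.9318431  2.0650620
#>   Km1  0.2817114  0.3388372
#>    V2 13.1729713 17.7689799
#>   Km2  0.6170630  3.1795852
#>     T  2.0000000  3.5000000

compare_models(fit_single_mm(assay), fit)
#> # A tibble: 1 × 4
#>   aicc_mono aicc_two delta selected
#>       <dbl>    <dbl> <dbl> <chr>
#> 1     -5.98    -153. -147. two_stage
```

Reading the output: the five generating constants are recovered within
noise (`V1` 1.99 ± 0.07 vs 2.02 truth; the threshold lands exactly on the
2 mM candidate), the 95% intervals for the low-affinity pair are wide —
`Km2` is only weakly identified below 10 mM — and the AICc difference of
−147 says the biphasic model is overwhelmingly preferred over a single
Michaelis–Menten curve for these data. `tidy(fit)`, `glance(fit)`,
`autoplot(fit)` and `plot_t_profile(fit)` give the broom-style tables and
diagnostic plots.

Metabolite analytics work the same way on tidy tables
(`treatment, organ, replicate, analyte, concentration`):

```r
tab <- simulate_metabolites(metabolite_design(), seed = 1)
pair_ratio(tab, "Gln", "Glu")      # per-replicate Gln:Glu ratios
total_faa(tab, unique(tab$analyte)) # per-sample free-amino-acid totals
fcm <- log2fc_matrix(tab)           # heat-map log2FC vs across-treatment mean
autoplot(fcm)
```

A command-line interface wraps the same functions
(`inst/cli/ninflux.R simulate-influx | fit-influx | simulate-metabolites |
analyze-metabolites`); every run echoes its effective configuration and
seed so outputs are reproducible.

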