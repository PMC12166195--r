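---
title: "Biphasic Michaelis-Menten analysis of root nitrogen influx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biphasic Michaelis-Menten analysis of root nitrogen influx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ninflux)
library(dplyr)
```

## The model

Short-term nutrient influx into plant roots is classically biphasic: a
saturable high-affinity transport system (HATS) dominates at low external
concentration, and a low-affinity system (LATS) takes over as concentration
rises. `ninflux` represents this with a two-stage Michaelis-Menten rate law
in which the low-affinity phase switches on only above an activation
threshold $T$:

$$
v(S) \;=\;
\begin{cases}
\dfrac{V_1 S}{K_{m1} + S} & S < T\\[2ex]
\dfrac{V_1 T}{K_{m1} + T} + \dfrac{V_2 (S - T)}{K_{m2} + S - T} & S \ge T
\end{cases}
$$

with $S$ the external concentration (mM), $v$ the influx rate
($\mu$mol g$^{-1}$ DW h$^{-1}$), $(V_1, K_{m1})$ the high-affinity phase and
$(V_2, K_{m2})$ the low-affinity phase. The assumptions are:

* below $T$, only the high-affinity transporter is active;
* at $T$ the high-affinity contribution freezes at its plateau value
  $V_1 T / (K_{m1} + T)$ and all additional uptake is carried by the
  low-affinity phase acting on the excess concentration $S - T$;
* the curve is therefore continuous at $T$ *by construction* — continuity
  is structural, never enforced numerically;
* phase identity follows the convention $K_{m1} \le K_{m2}$ (small $K_m$ =
  high affinity). User-supplied parameter sets violating it are normalised
  by swapping phases with a warning.

A nearly linear low-affinity response — as seen for ammonium uptake, where
the second phase hardly saturates over the assay range — is represented by
the same saturable form with a large $K_{m2}$, not by a separate linear
term: on $S \le 10$ mM with $K_{m2} \approx 81$ mM the Michaelis-Menten
term is indistinguishable from a straight line, and keeping one functional
form keeps the estimator uniform.

Rates are expressed per hour throughout. Influx assays typically incubate
for ~10 minutes; whether and how the assay time is normalised to one hour
is the data producer's responsibility (`ape_to_influx()` takes the duration
in hours, so a 10-minute assay passes `duration_h = 1/6`). The model layer
is unit-agnostic beyond internal consistency.

## Fitting

`fit_two_stage()` estimates all five parameters from replicate-level
records by unweighted nonlinear least squares. Three structural choices
matter:

**The threshold is profiled, not jointly optimised.** The SSE surface is
non-smooth in $T$ (records switch branches as $T$ crosses observed
concentrations), so gradient methods are unreliable there. Instead $T$
ranges over a finite candidate set — by default the observed distinct
concentrations plus the midpoints between consecutive ones — and the
remaining four parameters are optimised at each fixed $T$. Ties in the
profile break toward the smallest $T$. The default candidates contain the
observed concentrations, so a threshold that coincides with a grid point
(the usual design) is recoverable exactly.

**Variable projection.** For fixed $(T, K_{m1}, K_{m2})$ the model is
linear in $(V_1, V_2)$:
$v = V_1 f_1(S) + V_2 f_2(S)$ with
$f_1 = S/(K_{m1}+S)$ below $T$ and the plateau above, and
$f_2 = (S-T)/(K_{m2}+S-T)$ above $T$ (zero below). The conditional
optimum of the rates is a nonnegative linear least-squares solve, leaving
only a 2-D search over $(\log K_{m1}, \log K_{m2})$, performed by a
Nelder-Mead simplex. This removes two dimensions, makes the initialisation
problem trivial for the rates, and is why a full profiled fit takes
milliseconds. The inner loop is compiled (C++), which is what makes the
bootstrap calibration study below practical on one CPU.

**Initialisation and bounds.** The $K_{m1}$ start comes from a Hanes-Woolf
linearisation ($S/v$ regressed on $S$) of the records below the candidate
threshold; the $K_{m2}$ start from the exact two-point solution of the
upper phase on the two largest concentrations after subtracting the
estimated plateau. All parameters are bounded to $(10^{-6}, 10^{4})$ in
native units, imposed by clamping on the log scale. The phase convention
$K_{m1} \le K_{m2}$ is enforced inside the optimiser by projecting the
search onto that half-space, so a fitted object never needs a
curve-altering swap. Noise-free data on the 13-point assay grid are
recovered to relative error $\sim 10^{-7}$ for all four rate constants
(and exactly for $T$).

For the single-phase model, `fit_single_mm()` applies the same variable
projection in one dimension: $V$ is solved linearly and $\log K_m$ is
optimised by golden-section search, bracketed both around the Hanes-Woolf
estimate and over the full bounds, keeping the better optimum.

Fitting uses all replicate-level points rather than concentration means:
this preserves the degrees of freedom that the AICc comparison and the
bootstrap rely on, and weights concentrations by their actual replication.
The loss is unweighted (homoscedastic) SSE; under the default
multiplicative noise model a weighted loss would be more efficient, but
the unweighted form is the plain reading of "nonlinear least squares" for
this assay and keeps the estimator free of a noise-model assumption.

## Model comparison

`compare_models()` contrasts the single-phase ($k = 2$) and two-stage
($k = 5$) fits by the small-sample corrected Akaike criterion for
least-squares fits,

$$\mathrm{AICc} = n \ln(\mathrm{SSE}/n) + 2k + \frac{2k(k+1)}{n-k-1},$$

selecting the smaller value. AICc was chosen over an F-test because it
does not require the models to be strictly nested in the tested parameter
and it penalises the five-parameter model appropriately at the $n = 52$
scale of a standard assay. The comparison refuses datasets too small for
the correction ($n \le k + 1$) and refuses fits computed on different data
(checked by an order-invariant fingerprint).

## Bootstrap uncertainty

`bootstrap_ci()` uses case resampling stratified within concentration
levels: each resample redraws, with replacement, the replicates observed
at each concentration, preserving the assay design exactly. A residual
bootstrap was rejected because the error structure of IRMS-derived rates
(variance roughly proportional to signal, truncation at zero) is not known
well enough to recentre residuals honestly. Intervals are percentile
intervals from the successful refits; refits warm-start at the original
$(K_{m1}, K_{m2})$ and profile the same threshold candidates. If more than
20% of refits fail the result is flagged with a warning and the intervals
use the successful draws only.

The calibration study in the test suite simulates 500 assays from the
nitrate parameter set under the default design (13 concentrations, 4
replicates, multiplicative noise with CV 0.05) with 200 resamples each,
and checks the empirical coverage of the 95% interval for $V_1$ against
the nominal band. Users should know that the percentile interval
under-covers in this regime: with 4 replicates per stratum the
within-stratum bootstrap underestimates sampling variance (the classical
$(n-1)/n$ shrinkage; the bootstrap-to-sampling SD ratio measures about
0.9 here), interval widths are themselves noisy at 4 replicates, and for
the nitrate curve $V_1$ is partly an extrapolation (the largest
sub-threshold rate reaches only about three quarters of $V_1$, and the
estimate is strongly correlated with $K_{m1}$). The measured coverage for
that design is in the mid-80s percent rather than 95%. The effect is a
property of the small-replicate case bootstrap, not of the optimiser —
refits at full optimisation effort give the same coverage — and it is
much milder when saturation is observed nearly directly, as in the
ammonium design where the high-affinity phase saturates far below the
threshold. Treat the percentile intervals at this replication level as
approximate, and prefer more replicates (or profile-likelihood intervals,
out of scope here) when calibrated uncertainty matters.

## The simulators

`simulate_influx()` emulates the influx assay: by default the 13-point
concentration grid from 0.01 to 10 mM with 4 replicates per concentration,
rates drawn from the two-stage law under multiplicative normal noise with
CV 0.05, truncated at zero. The multiplicative form reflects that
IRMS-derived rates have errors roughly proportional to signal; the CV is a
realistic relative error for such assays. What the simulator does *not*
emulate: plant-to-plant random effects shared across a plant's
measurements (each record is independent), any systematic bias from
incomplete root washing, natural-abundance background, or drift across
assay batches. Round-trip tests therefore demonstrate estimator
correctness and calibration under the stated noise model, not robustness
to those real-data features.

`simulate_metabolites()` emulates a treatment $\times$ organ $\times$
replicate $\times$ analyte concentration table under the five
ammonium:nitrate ratio treatments (100:0 to 0:100 of 2.86 mM total N, six
replicates). Draws are normal around the design means with SD = CV
$\times$ mean (default CV 0.10), truncated at zero; a truncated normal was
preferred to a lognormal for direct moment control, and the choice is
recorded in the table's provenance attribute. The default mean table
(`default_metabolite_means()`) is synthetic: it reproduces qualitative
patterns (theanine and arginine rising with the ammonium share, glutamine
peaking at the 25:75 treatment) at plausible magnitudes for tea tissues,
and is intended for testing analytics, not for biological inference.

`ape_to_influx()` is the minimal isotope-dilution conversion
$(\mathrm{APE}_{sample}/\mathrm{APE}_{source}) \cdot N_{total} / t$; it
assumes background subtraction has already produced the sample's atom
percent *excess*, and natural-abundance correction is deliberately out of
scope.

## Metabolite analytics

* `pair_ratio()` computes analyte ratios (e.g. Gln:Glu, Gln:Thea) *per
  replicate*, matching how such ratios are shown as per-replicate points;
  a ratio of treatment means is deliberately not the default. Nonpositive
  denominators yield flagged missing values, never silent drops.
* `total_faa()` sums a stated analyte set per sample.
* `log2fc_matrix()` computes the heat-map statistic: each value divided by
  its row's across-treatment mean, then $\log_2$. The grand mean is the
  mean of the treatment means (equal treatment weighting), which makes the
  row normalisation exact — the plain treatment-mean fold-changes of every
  row average to exactly 1 — and is robust to unequal replicate counts.
  Because a per-sample reading of "divided by the mean over treatments" is
  also defensible, both forms are emitted (`by_treatment` and
  `per_sample`), and `grand_mean = "samples"` switches the normalising
  basis. Zero-mean rows propagate as missing cells with a warning, never
  as zeros.
* `content_from_concentration()` is the concentration $\times$ biomass
  product that separates tissue concentration from whole-organ content.

Group-difference testing (e.g. Tukey's HSD letters) is out of scope by
design: the analytics emit tidy tables that drop straight into any
standard testing function.

## Numerical choices and degenerate inputs

* Log-scale optimisation for all $K_m$ parameters (they are
  scale parameters spanning orders of magnitude).
* Nelder-Mead relative tolerance $10^{-13}$ with a restart for final
  fits; $10^{-9}$ without restart for bootstrap refits, which are
  warm-started (tolerances much below $10^{-9}$ sit under the numerical
  noise floor of the clamped linear solves and only burn iterations —
  measured coverage is identical at full optimisation effort).
* Profile ties break toward the smallest $T$ (a strict-improvement rule
  over candidates scanned in ascending order).
* All-zero rate vectors are a degenerate-data error; fewer than 3 (mono)
  or 5 (two-stage) distinct concentrations is an insufficient-data error;
  a candidate set leaving fewer than 2 distinct concentrations on either
  side of every candidate is an insufficient-data error.
* When the data carry no second phase, the nonnegative linear solve
  clamps $V_2$ to zero and the fit degrades gracefully to the
  single-phase curve; with threshold candidates beyond the largest
  concentration the two-stage model reproduces the mono fit exactly,
  which is also how the nesting property (two-stage SSE $\le$ mono SSE)
  is realised.
* `brute_force_fit()` is an optimizer-independent oracle for tests:
  exhaustive SSE evaluation over a parameter grid, refusing more than
  $10^7$ points.

## Problem sizes in the validation suite

The suite fits hundreds of simulated assays: round-trip recovery on the
full 13 $\times$ 4 design, dominance and oracle checks on a handful of
seeds, and the bootstrap calibration at 500 simulations $\times$ 200
resamples (about 100,000 profiled refits) — sizes chosen so the whole
suite completes in minutes on a single core while keeping the coverage
estimate's binomial error near one percentage point.

## Limitations

* No hierarchical (per-plant) error structure; replicates are exchangeable
  within a concentration.
* No more than two phases, no temperature or pH dependence, no
  mechanistic transporter (AMT/NRT) modelling.
* The threshold estimate's resolution is the candidate-grid resolution;
  between-candidate values of $T$ are not considered.
* Percentile bootstrap intervals inherit small-sample undercoverage at 4
  replicates per concentration (see above).
* The metabolite simulator's mean table is synthetic and qualitative; it
  validates analytics code, not biology.
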