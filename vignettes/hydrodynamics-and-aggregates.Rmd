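---
title: "From bioreactor hydrodynamics to cell-aggregate size distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From bioreactor hydrodynamics to cell-aggregate size distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kolmoagg)
```

## The problem

Suspension-grown mammalian cells (HEK293 being a prominent example) tend to
aggregate, and aggregation limits cell density at scale. The mechanical
environment of the bioreactor — quantified by the specific power input $P/V$
and by the turbulent eddy-size spectrum — is the main process handle on
aggregation. This package implements the computational chain that connects a
CFD characterisation of a bioreactor to the expected aggregate-size
distribution of the culture:

1. **Field post-processing**: exported per-cell turbulence fields become
   volume-weighted dissipation and Kolmogorov-length statistics.
2. **Mesh verification**: a grid-convergence-index (GCI) study quantifies
   the spatial discretisation error of those statistics.
3. **Operating-point correlations**: closed-form checks (phase number,
   axial Froude number, empirical power correlations, oxygen ceiling)
   situate the simulated operating point.
4. **Aggregate model**: cluster sizes follow a geometric distribution whose
   parameter $p$ — the fraction of non-aggregated cells — is linearly
   predictable from the mean Kolmogorov length, giving an in-silico
   aggregate-size prediction.

## Hydrodynamic statistics

A `flow_field` is a list of finite-volume cells $(V_i, k_i, \omega_i)$ with
a declared total liquid volume $V$. Under $k$–$\omega$-family turbulence
closures the local dissipation rate is not transported directly; it is
recovered as $\epsilon_i = \beta^* k_i \omega_i$ with $\beta^* = 0.09$.
From it follow:

* the **specific power input** by volume integration,
  $P/V = \sum_i \epsilon_i V_i \rho / V$, and independently from a torque
  $M$ as $P/V = 2\pi n M/V$. The dissipation route systematically
  underestimates the torque route in RANS solutions (literature reports
  ratios around 0.6); both are therefore reported.
* the **Kolmogorov length** $\lambda_{k,i} = (\nu^3/\epsilon_i)^{1/4}$, the
  smallest eddy scale. Eddies smaller than a cell (≈ 15.5 µm) or a small
  aggregate (≈ 33 µm for a compact 3-cell cluster) are the damaging ones,
  so the package reports the volume-weighted mean, the volume-weighted
  median, and the volume fraction below user-supplied critical lengths
  (a CDF in the critical length).
* the **hydrodynamic heterogeneity** $\Phi = \epsilon_{max}/\bar\epsilon$.
  Shaken systems are homogeneous ($\Phi \sim$ 1–20), stirred tanks
  concentrated ($\Phi \sim$ 10–400). The maximum is the raw cell-wise
  maximum by default; because single-cell outliers dominate CFD maxima, a
  quantile-trimmed variant (`max_quantile = 0.999`) is available.
* the **Q-criterion**, $Q = \frac12[(\mathrm{tr}\nabla v)^2 -
  \mathrm{tr}(\nabla v \nabla v)]$, for vortex identification when
  velocity gradients are exported.

Numerical choices worth stating:

* All reductions normalise by $\sum_i V_i$, not the declared $V$: exported
  subsets of multiphase solutions routinely lose cells, and normalising by
  the declared volume would silently bias every statistic. Mismatches above
  1e-6 relative warn; above 1e-2 they error.
* Quiescent cells ($\epsilon_i = 0$) have $\lambda_k = \infty$. They are
  clamped into the topmost histogram bin and reported as a quiescent-volume
  diagnostic, so the volume fractions always sum to 1; dropping them would
  break that invariant.
* The default $\lambda$ histogram uses 200 logarithmic bins spanning
  $[\min \lambda / 1.05,\ \max \lambda \cdot 1.05]$; the source figures
  give no binning, and a log grid resolves both tails of the strongly
  skewed distribution.
* A provided $\epsilon$ column always wins over $(k, \omega)$; per-record
  mixing is rejected as almost certainly an export error.

## Grid-convergence verification

`analyze_gci()` runs the Richardson-extrapolation bookkeeping over every
consecutive mesh triplet of a coarse-to-fine series: effective refinement
factors $r = (n_{fine}/n_{coarse})^{1/3}$ (cube root for 3D; a `dim = 2`
mode exists), relative errors $\epsilon_{mn} = |f_m - f_n|/|f_m|$
normalised by the **coarser** value, the observed order $p$, the GCI
$= 100 F_s \epsilon_{mn}/(r^p - 1)$ with safety factor $F_s = 1.25$, and
the asymptotic-range ratio
$GCI_{coarse}/(r_{coarse}^{\,p}\, GCI_{fine})$, which approaches 1 inside
the asymptotic range.

The coarser-value normalisation and this ratio convention were pinned by
reproducing the published flask mesh study (relative errors
$3.24, 4.52, 4.03, 2.06 \times 10^{-2}$; ratio 0.73 for the middle case);
the alternative fine-value normalisation contradicts those entries.

The observed order solves the non-constant-$r$ relation
$\frac{e_{21}}{e_{32}} = r_{32}^p \frac{r_{21}^p - 1}{r_{32}^p - 1}$ by a
damped, sign-corrected fixed point (tolerance $10^{-10}$, cap 200
iterations); oscillatory convergence (sign change of successive
differences) is flagged rather than silently returning NaN, and
mesh-converged triplets with zero differences report a zero error band and
no order. The published apparent orders for these tables are **not**
reproducible from the published quantity-of-interest values by this (or
any standard) formulation — the original solve is unstated — so printed
orders are treated as anchors only, and correctness is established by
recovering known orders $p \in \{0.5, 1, 2, 3\}$ from synthetic power-law
series to $10^{-6}$, cross-checked against an independent root-scan oracle
in the tests.

## Operating-point correlations

For orbitally shaken flasks, in-phase operation requires both
$Ph = (d_0/d)(1 + 3\log_{10} Re_f) > 1.26$ (with the film Reynolds number
$Re_f$ built from the fill volume and flask diameter) and
$Fr_a = (2\pi n)^2 (d_0/2)/g > 0.4$. Two printed-form ambiguities were
resolved by requiring the published operating-point values to reproduce:
the Froude form above returns the published 0.47 at 130 rpm and 50 mm for
any $g \in [9.78, 9.83]$, and the $+3\log_{10}$ sign is forced by the
published $Ph = 5.48 \gg 1.26$ (the printed minus sign would make $Ph$
negative). The flask's maximum inner diameter is never published; with the
nominal 0.101 m of a 500 mL Erlenmeyer the phase number is ≈ 5.1 and the
unbaffled power correlation
$P/V = (70 Re^{-1} + 25 Re^{-0.6} + 1.5 Re^{-0.2})\,\rho n^3 d^4 / V^{2/3}$
gives ≈ 86 W/m³ against the published 82.4–83.7 W/m³; these are treated as
band anchors, not exact values.

For stirred tanks: $Re_m = N d_s^2/\nu$, $Ne = P/(\rho N^3 d_s^5)$,
$v_{tip} = \pi d_s N$, and the published Minifors-2 tip-speed correlation
$P/V = 131.79\, v_{tip}^{2.767}$. The package always computes $Re_m$ from
the supplied fluid properties; the published $Re_m = 13\,474$ at 100 rpm
is only consistent with room-temperature water viscosity, not with the
stated 37 °C properties (which give 17 304), and this discrepancy is
documented rather than patched.

The oxygen ceiling equates transfer and uptake:
$c_x = k_La (c^*_{O2} - c_{O2})/q_{O2}$, with $c^*_{O2}$ from the Tromans
temperature correlation, by default for dry air at 1 atm
($p_{O2} = 0.2095$ atm); optional humidity and CO₂ corrections reduce the
effective partial pressure and are off by default. With $k_La = 16\,
h^{-1}$, $q_{O2} = 1.85\times10^{-13}$ mol h⁻¹ cell⁻¹ and air saturation
at 37 °C this bounds the supportable density at about
$1.9\times10^7$ cells/mL — an order-of-magnitude statement, since the
original solubility assumptions are not recoverable.

## The geometric aggregate model

Observed cluster-size counts are fitted by
$f(n) = (1-p)^{n-1} p$, $n \ge 1$:

```{r}
cc  <- gen_clusters(5000, p = 0.655, seed = 1)
fit <- geom_cluster_fit(cc, estimator = "mle")
summary(fit)
```

The parameter has two readings that differ mathematically: the fraction of
**cells** not present as aggregates (per-cell singles fraction — the
default, matching the biological interpretation of $p$ in measured count
tables) and the size-1 probability of the **cluster** distribution
(per-cluster fraction; for an i.i.d. geometric cluster sample the per-cell
fraction estimates $p^2$ rather than $p$, which is why the MLE is the
right choice above). The maximum-likelihood estimate
$\hat p = N_{clusters}/N_{cells}$ (inverse mean cluster size) is reported
alongside both; their relative differences are themselves informative
(published values differ by 0.3–6 %).

Goodness-of-fit uses the Pearson $\chi^2$ and the G (log-likelihood-ratio)
statistics over bins pooled from the tail until every expected count
reaches 5 (standard practice; the source states no pooling rule), with one
degree of freedom subtracted when $p$ was estimated from the same data
(the source states no df convention). The tests are verified to be
calibrated — empirical type-I error within [0.03, 0.07] at nominal 0.05
over 2000 replicates of 500 clusters — and to reject a half-and-half
geometric mixture with power above 0.9 at the same sample size. At the
sample sizes of real aggregate counts (thousands of cells) even practically
irrelevant deviations are statistically significant; the model's value is
the two-parameter-free prediction, not the p-value.

The **Kolmogorov-length link** closes the chain: across cultivation systems
the measured $p$ falls on a line in the volume-averaged Kolmogorov length,
$p = a + b\bar\lambda_k$, with published coefficients $a = 0.92$,
$b = -4589\ \mathrm{m^{-1}}$ (the default `lambda_link()`). `predict_p()`
clamps predictions to $[0,1]$ with a warning — the line is unphysical
beyond $\bar\lambda_k \approx 2\times10^{-4}$ m — and
`predict_distribution()` composes the link with the pmf. Refitting from
user observations is ordinary least squares of $p$ on $\bar\lambda_k$
(`lambda_link(lambda, p)`). The published 5-point fit cannot be reproduced
exactly because the stirred-tank predictor values behind it are not
published; the two published flask observations give a two-point line of
slope −5379 and intercept 0.984, and the default link reproduces both
measured fractions within 0.05.

```{r}
predict_p(c(6.123e-5, 1.025e-4))
predict_distribution(6.123e-5, n_max = 5)
```

## Growth metrics

$\mu_{max}$ is the maximum over sliding windows (default width 48 h, the
typical 24–72 h exponential span) of the OLS slope of $\ln$ VCD against
time — OLS rather than two-point ratios for noise robustness. The peak VCD
is gated on viability ≥ 95 % (the convention of the source experiments) to
exclude spurious late readings, falling back to the unconditional maximum
with a warning. Cell-diameter statistics report raw mean/SD plus a 1 µm
class histogram (the imaging counter's resolution); classes are
left-closed with integer centres, implemented as `floor(x + 1/2)` because
`round()`'s tie-to-even would split the class boundaries inconsistently.

## What the synthetic generators emulate — and what they do not

`gen_flowfield()` draws log-normal dissipation fields — the standard
positively skewed model for dissipation in agitated vessels — and imposes
the two moments the analysis consumes: the volume-weighted mean (matched
multiplicatively to 0.1 %) and the max/mean heterogeneity (matched by
bisection on the log-scale spread to 5 %). `k` is back-filled as
$(\epsilon L)^{2/3}$ with a nominal length scale $L = d_s/10$; only the
product $k\omega$ is constrained, so $L$ is a documented convention.
`gen_clusters()` draws i.i.d. geometric sizes; `gen_mesh_series()`
evaluates $f_\infty + C h^p$ at $h = n_c^{-1/3}$; `gen_growth()` produces
exponential-then-declining daily curves with multiplicative log-normal
noise; `gen_diameters()` draws truncated normals on the 2–40 µm instrument
range. All generators are pure functions of their arguments and seed, and
restore the caller's RNG state.

What they do **not** emulate: spatial correlation of dissipation,
the bimodal impeller/bulk structure of stirred fields, transient shaking
phases, measurement-specific aggregate-segmentation artefacts, or any
departure of real cluster data from geometric form. Passing tests
therefore demonstrate the correctness of the estimators and reductions
under the stated statistical structure, not the physical fidelity of any
particular CFD solution.

## Problem sizes and defaults used in validation

The shipped validation uses fields of 400–2000 cells, cluster samples of
500–100 000, 2000-replicate calibration loops, and the published 4- and
5-mesh series; these sizes hold every Monte-Carlo tolerance stated above
while keeping the whole suite interactive. Key defaults: $\beta^* = 0.09$;
$F_s = 1.25$; GOF pooling floor 5; viability floor 95 %; $\mu_{max}$
window 48 h; $g = 9.80665$ m/s² (configurable; all published comparisons
hold for any $g \in [9.78, 9.83]$); link coefficients $(0.92, -4589)$.

## Known limitations

* The artifact consumes exported fields; it does not solve flow equations,
  reconstruct free surfaces, or process PIV imagery.
* Only unbaffled-flask power and phase correlations exist; baffled flasks
  have no closed form and must come from CFD or measurement.
* The close-packing diameter is defined for 3-cell clusters only (the only
  published case); general-$n$ packings are out of scope.
* The aggregate model is a steady-state description at peak cell density;
  no aggregation/breakup kinetics are modelled.
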