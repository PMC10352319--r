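---
title: "Reactive-nitrogen control pathways for PM2.5 mitigation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reactive-nitrogen control pathways for PM2.5 mitigation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrpathways)
```

## The problem

Nitrogen oxides (NOx) and ammonia (NH3) -- together "reactive nitrogen" (Nr)
-- are precursors of secondary inorganic aerosol (SIA: sulfate, nitrate,
ammonium), a major component of European fine-particulate (PM2.5) pollution.
Whether a regulator should push NOx or NH3 controls is not obvious: the two
species interact through a strongly nonlinear chemistry, abatement costs
differ by an order of magnitude, and effectiveness changes as cuts deepen.
This package provides the full analysis chain for that question on a
self-contained synthetic domain: scenario response analysis, exposure and
health-burden metrics, efficiency and chemical-regime diagnostics, and
gradient-based pathway optimization on the (NH3, NOx) control plane, with
abatement costs.

## The SIA equilibrium surrogate

A chemistry-transport model is the natural provider of concentration fields
per control scenario, but the analysis layer is agnostic to the provider. We
therefore generate fields from a closed-form equilibrium surrogate that
encodes the regime structure the analysis depends on. Per grid cell, month
and vertical layer, with NH3 reduction $x$ and NOx reduction $y$:

* total ammonia availability $A = a_{tot}\,E_{NH3}\,(1-x)$,
* total nitrate availability $T\!N = n_{tot}\,E_{NOx}\,(1-y)^{p_{ox}}$,
* ammonia neutralizes sulfate first: $NH_4^{sulf} = \min(A,\,2\,s_{fix})$,
* free ammonia $FA = \max(0,\,A - 2\,s_{fix})$ forms ammonium nitrate:
  $NO_3^- = \varepsilon\,\mathrm{smoothmin}(FA,\,T\!N)$,
* $PM_{2.5} = \text{background} + 96\,[SO_4^{2-}] + 62\,[NO_3^-] + 18\,[NH_4^+]$
  (molar concentrations in umol/m3, molecular weights in g/mol).

The exponent $p_{ox} \ge 1$ (default 1.6) is the one tunable that stands in
for oxidant feedback: deeper NOx cuts yield less nitric acid per unit NOx,
so the marginal NOx efficiency declines. No functional form for this
feedback is established; a single curvature exponent reproduces the
qualitative decline and keeps the surrogate analytically transparent. The
smooth minimum (default sharpness 150 per umol/m3) gives kink-free response
surfaces for interpolation and gradient work; the exact minimum
(`sharpness = Inf`) is available for analytic tests, where mass closure,
the charge-style balance $NH_4^+ = 2\,SO_4^{2-,neut} + NO_3^-$, and the
identity $G = FA/T\!N$ hold exactly.

Monthly structure: four represented months (January, April, July, October),
whose arithmetic mean defines the "annual mean" throughout. NH3 emissions
peak in April, NOx in January; the ammonium-nitrate yield `eps` is low in
July (0.35) because heat and dryness suppress nitrate aerosol -- months with
`eps < 0.05` are flagged as unreliable for the G diagnostic. Secondary
organic aerosol in the background mass is composed as 3 x OC in July and
2 x OC otherwise.

### Default calibration

The defaults describe a Western/Eastern European contrast, chosen to
reproduce magnitudes a reader would recognize: emission totals 4.4 Tg N (NH3) and 3.7 Tg N (NOx) per
year, higher emission densities in the West; baseline regional-mean PM2.5
near 8 (West) and 6 (East) ug/m3; a base ammonia-saturation ratio G of
about 4.6 in the West and 2.0 in the East (HNO3-limited everywhere); and an
Nr share of PM2.5 of roughly 28% West / 12% East. These are soft
calibration targets of the generator, not test oracles. The default grid is
10 x 14 cells; tests use 6 x 8. All generators take explicit seeds and
restore the caller's RNG state.

## Health burden (GEMM)

The Global Exposure Mortality Model hazard ratio for NCD+LRI mortality is

$$RR(c) = \exp\!\Big(\theta\,\log(z/\alpha + 1)\,/\,
  \big(1 + e^{-(z-\mu)/\upsilon}\big)\Big),\qquad z = \max(0,\,c - 2.4),$$

per age group, with a counterfactual threshold of 2.4 ug/m3 below which no
impact occurs. Two readings of the published formula exist; the one
used here, $\log(z/\alpha + 1)$, is the only one with $RR = 1$ at the
threshold and continuity above it. Attributable deaths use the
attributable-fraction form
$\sum_i Base_i\,Pop_i\,(1 - 1/RR_i)$; the raw $1/RR$ form (which returns
total, not excess, mortality) is kept behind `as_printed = TRUE` for audit.
Uncertainty: only $\theta$ is sampled, independently per age group, from
$N(\theta, se_\theta)$, ten thousand draws by default; the 95% CI is the
empirical 2.5/97.5 percentile range. GEMM coefficients are user-supplied
via CSV; the bundled table is a synthetic fixture (age-declining $\theta$,
common shape constants) and must not be read as published values. Twelve
age groups are used (25-29 through 75-79, then 80+): carrying 5-year bins
to 85+ would need thirteen, so the oldest interval is left open.

## Exposure metrics

The N-share is $(PM^{base} - PM^{noNr})/PM^{base}$ per cell, aggregated as
area-weighted regional means (cell areas are spherical; the weighting
convention is ours). Annual-guideline achievement is the area fraction
strictly below 5 ug/m3; daily exceedance applies the 15 ug/m3 threshold to
the regional-mean daily series. True daily output does not exist in a
four-month equilibrium world, so daily values are synthesized as
mean-preserving lognormal fluctuations around monthly means with a
configurable coefficient of variation (default 0.4) -- this exercises the
daily-guideline logic but carries no meteorological persistence, so daily
statistics should be read as illustrative. Required-reduction maps invert
the monotone response per cell by bisection to 1e-3 in the control
fraction (ties resolve to the smaller reduction); cells at or above the
guideline even under full controls are flagged unreachable.

## Efficiency and regime diagnostics

The instant efficiency $\beta$ is the percent PM2.5 decrease per 1%
emission decrease, evaluated on an 11-level grid (0%, 10%, ..., 100%)
interpolated from the simulated levels (0/30/60/80/100%) by
shape-preserving piecewise cubics (PCHIP). The stencils are forward at
level 1, centered (20% span) at levels 2-10, backward at level 11 -- the
published index pattern at the endpoints only parses as one-sided
differences, and that is what is implemented. Emissions are linear in the
control level, so each stencil denominator is the level gap. Regional
$\beta$ defaults to the $\beta$ of the regional-mean curve; per-cell series
are available, and their tipping-point distribution provides the spatial
spread.

The G ratio $([NH_3]+[NH_4^+]-2[SO_4^{2-}])/([HNO_3]+[NO_3^-])$ (molar)
diagnoses the chemical regime: above 1, SIA formation is HNO3-limited and
NOx cuts bite; below 1 it is NH3-limited. Cells with total nitrate below
1e-9 umol/m3 are masked rather than infinite. G can be negative where
ammonia cannot even neutralize sulfate; monotonicity of G in NOx cuts is
only guaranteed where G > 0. Mass-based $\beta$ and molar G answer
different questions; `molar_normalize()` divides $\beta$ by total molar N
emissions to put the two species on a per-mole footing. In the sharp-min
surrogate with fully neutralized sulfate, the per-mole sensitivities of
PM2.5 to ammonia and to nitrate availability cross exactly at $G = 1$
(`g_equivalence_point()` locates this by brute-force sweep + bisection).

Tipping points -- the reduction depth where $\beta_{NH3} - \beta_{NOx}$ or
$G - 1$ first crosses zero -- are located by linear interpolation between
adjacent levels, reporting the first crossing from the 0% side (the
narrative quantity is "when does NH3 control start to win"); no crossing on
[0, 100%] yields an unreachable flag.

## Response surface and pathways

`fit_response_surface()` is the package's central fit. The 13-scenario
design covers three rays of the control plane (NH3-only axis, NOx-only
axis, joint diagonal). Each ray is PCHIP-interpolated; the interior is a
transfinite blend $f_x(x) + f_y(y) - base + s(\min(x,y))$, with $s$ the
diagonal residual at the diagonal knots. The blend is exact on all three
rays and exact everywhere for ray-consistent additively separable inputs.
The blend coordinate $\min(x, y)$ (the joint-control depth shared by both
species) keeps the blend monotone wherever the diagonal falls at least as
fast as each axis; where strong sub-additivity still produces local dips
(deep NH3 cuts make further NOx cuts worthless, which three rays cannot
fully encode), the grid is projected to the smallest monotone majorant --
dips are filled upward, and ray/node values, which dominate their own
quadrant, are never altered. `predict()` interpolates this monotonized grid
bilinearly. Against the surrogate evaluated directly, the interior error on
the default fixture stays within the configured tolerance of 20% of the
response range (the property suite checks this bound; node values are
reproduced exactly).

Gradients use centered differences in the interior and one-sided stencils
at the edges, consistent with the $\beta$ stencils, so the axis
restrictions of the gradient reproduce the per-axis efficiencies up to the
base normalization.

`steepest_descent_path()` walks the lattice from (0, 0), taking at each
node the 10% move (NH3 or NOx) with the larger surface decrease, ties
toward NH3, stopping at (1, 1) or when no move decreases the surface. The
10% lattice matches the diagram resolution and makes exhaustive
verification feasible: `path_optimality_gap()` enumerates all monotone
lattice paths on a 6 x 6 corner and reports, per path length, the gap to
the enumerated optimum. For diminishing-returns surfaces greedy is
lattice-optimal (and the tests require a zero gap there); for
increasing-returns surfaces -- precisely the NH3 regime -- greedy can lag at
intermediate lengths, and the gap is reported rather than hidden.

Cost curves are built from anchor points (origin-anchored, strictly
increasing, convex) with a Schumaker-style convexity-preserving C1
quadratic spline -- monotone cubics (PCHIP) preserve monotonicity but not
convexity, which matters for marginal-cost reasoning. Beyond the last
anchor the curve continues linearly at the spline's end slope, capped at
50% reduction per species: cost data above currently feasible levels are an
extrapolation and are treated as such. Costs add across species (no joint
technologies). The cost-effectiveness surface is cumulative cost divided by
cumulative abatement from base, masked at the origin.

`cost_optimal_path()` is a greedy walk choosing the move with the lowest
incremental cost per incremental microgram abated. Stop rule: the path ends
when the best remaining move is no better than a move it previously passed
over -- once extending requires an option already rejected in favor of
cheaper abatement, the efficient frontier of the diagram is exhausted. With
separable costs this fires exactly at a species cap when the path would be
forced onto the other species. On the bundled Western-Europe anchor
calibration (10%/30% costs of 0.08/1.1 billion euro for NH3 and 1.1/12.7
for NOx against abatements of 0.11/0.40 and 0.23/0.67 ug/m3) the path runs
along the NH3 axis to the 50% cap, and the NOx-to-NH3 cost-per-microgram
ratio at the anchor columns is 6.6-6.9.

## What the synthetic domain does and does not show

The generator emulates the statistical and chemical structure the analysis
assumes: log-normal co-located emission hotspots with a West/East contrast,
seasonal emission factors, sulfate-first neutralization, diminishing NOx
returns, age-structured population with rising NCD+LRI baseline rates. It
has no meteorology, transport, deposition, ozone chemistry, bidirectional
NH3 exchange, or real inventories; vertical structure is a simple
exponential decay of availabilities. Passing tests therefore demonstrate
the correctness of the analysis machinery on fields with the right
structure -- not that any particular European number is reproduced. The
published headline values that depend on a full chemistry-transport model
(regional PM2.5 reductions, absolute death counts, the 36%/18% and 73%/46%
tipping points) are out of reach by design; the analytic anchors (the 2.4
ug/m3 risk threshold, the G = 1 equivalence point, the published
cost-effectiveness ordering) are reproduced exactly and are what
`scripts/acceptance.R` recomputes.

## Numerical choices and problem sizes

Tolerances: bisection 1e-3 (control fractions), G-denominator mask 1e-9
umol/m3, stencil-oracle comparisons bounded by the centered-difference
truncation term with a numerically bounded third derivative (safety factor
1.5). Default problem sizes were chosen so the whole suite runs in seconds
on one core: 6 x 8 to 10 x 14 grids, 13-member ensembles, 10000 Monte Carlo
draws (the default; the pipeline uses 2000 unless asked otherwise),
enumeration on 6 x 6 lattices (252 paths). Full-pipeline runs are
byte-reproducible under a fixed seed; the manifest records the config hash
and package version. Gridded outputs are long-format CSV carrying the full
dimension set (scenario, month, level, lat, lon) at full float precision; a
documented schema rather than a binary format keeps every artifact
readable and diffable, and real model output can be supplied in the same
layout.

## Known limitations

* Three rays cannot identify a full two-species interaction surface; the
  residual interior error against the surrogate is intrinsic to the
  13-scenario design, not to the interpolation scheme.
* Greedy pathways are lattice-heuristics; global optimality is checked, and
  failures reported, only on small enumerable grids.
* The daily-exceedance machinery uses synthetic lognormal days without
  autocorrelation.
* The G diagnostic is a box-model concept; its regional aggregation loses
  extreme values, which is why the efficiency-based tipping point, not
  G = 1, is the recommended policy diagnostic.
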