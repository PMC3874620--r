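---
title: "Planning vitamin D fortification with fortiplan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning vitamin D fortification with fortiplan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fortiplan)
```

## The model

`fortiplan` answers a food-policy question: how much vitamin D must be
added per 100 g of a carrier food so that consumers reach either a daily
intake recommendation or a target serum 25(OH)D concentration, and what
are the consequences for consumers at the extremes of the consumption
distribution?

Everything rests on three deterministic formulas.

**Constant fortification** (intake-based, year-round): with recommended
intake $I_r$ (μg/day), actual intake from natural food and supplements
$I_a$ (μg/day), and daily carrier consumption $F_i$ (g/day),

$$f_c = \max\!\left(0,\ \frac{(I_r - I_a)\cdot 100}{F_i}\right)
\quad [\mu g\ \mathrm{per}\ 100\,g].$$

**Seasonally varying fortification** (serum-based): with serum target
$L_r$ (nmol/L), monthly baseline concentration $L_a(m)$, and conversion
factor $c_f$ (nmol/L serum rise per μg/day of vitamin D from fortified
food),

$$f_v(m) = \max\!\left(0,\ \frac{(L_r - L_a(m))\cdot 100}{c_f\, F_i}\right).$$

**Serum response**: the predicted concentration under a plan is

$$L_n(m) = L_a(m) + \frac{c_f\, F_i\, f(m)}{100}.$$

The model is an average-population model: it describes a representative
individual at a chosen consumption/intake percentile, not the
distribution of individual responses. The conversion factor is treated as
linear and season-independent.

## Parameters and their defaults

The packaged configuration (`inst/extdata/table1_defaults.yaml`) carries
the published inputs: carrier consumption at the 5th percentile, mean and
95th percentile by gender (bread 46/43, 180/134, 377/270 g/day for
men/women; milk 16/22, 222/203, 712/555; juice 0/0, 270/232, 1200/1000),
mean dietary vitamin D intake (men 3.4, women 2.8 μg/day), mean
supplement intake (0.3 μg/day), the intake targets (IOM 15, DGE 20,
upper level 100 μg/day), the serum targets (50 and 75 nmol/L), the
conversion factor $c_f = 2.32$ nmol/L per μg/day, and the safety
thresholds (100 μg/day intake, 500 nmol/L serum intoxication).

Two conventions govern how a scenario selects a single number from the
gendered table:

* **Carrier consumption**: the mean and high (p95) scenarios use the
  *higher*-consuming gender, which yields conservative (lower)
  fortification levels; the low (p5) scenario uses the *lower*-consuming
  gender, so that 95 % of the population at least reaches the target.
  Operationally this is a max/min rule, which also captures the one
  exception in the data — at the milk 5th percentile men (16 g) consume
  less than women (22 g).
* **Dietary intake**: the unweighted mean of the gender values
  ((3.4 + 2.8)/2 = 3.1 μg/day), plus the supplement mean, which is
  applied identically in every percentile scenario because no supplement
  percentiles are available.

The 5th/95th percentiles of dietary intake are not published; the fixture
ships clearly labelled synthetic placeholders (men 1.0/7.0, women 1.0/6.0
μg/day). Any conclusion that depends on them is ordering-only; the
package's tests assert envelope orderings, never absolute values, at
those percentiles.

## The synthetic baseline trajectory

The upstream serum model that supplies monthly baseline 25(OH)D values
per region is not published as numbers, only its annual mean (45 nmol/L)
and the fact of seasonal variation. `fortiplan` therefore generates
baselines from the minimal model consistent with that information, a
single-harmonic cosine

$$L_a(m) = \mu + o - A\cos\!\left(\frac{2\pi (m - m_0)}{12}\right),$$

with annual mean $\mu = 45$ nmol/L, additive regional offset $o = 0$,
trough month $m_0 = $ January, and amplitude $A = 17.2$ nmol/L. The
amplitude is *derived*, not observed: it is the value for which the
default pipeline reproduces the published January bread example
end-to-end ($L_a(\mathrm{Jan}) = 75 - 11.3 \cdot 2.32 \cdot 1.8 \approx
27.8$ nmol/L), obtained with `calibrate_amplitude(45, 1, 27.8, 1)`. The
true trough month of the upstream model is not recoverable from the
published numbers; January is the only month the worked example
constrains, and the symmetric cosine places the peak in July
(62.2 nmol/L).

What the generator emulates: the level, the seasonal swing, and the
winter trough of a German average-population baseline. What it does not
emulate: regional (federal-state) differences beyond a constant offset,
asymmetric rise/fall around the trough, year-to-year variation, and any
behavioural covariates of sun exposure. Tests passing against this
generator therefore validate the fortification arithmetic and the
plumbing, not the realism of any particular month's baseline — which is
why any observed 12-month vector can be supplied directly
(`serum_trajectory()` or a CSV via `read_trajectory_csv()`).

An optional Gaussian noise term (`noise_sd`, default 0 nmol/L) exists for
robustness testing only; it is seeded and off in all default analyses.

## Clustering monthly levels

A fortification level that changes every month is industrially
impractical, so monthly requirements are merged into two blocks:

* the **summer cluster** is the longest run of consecutive months
  (circular, so a November–February run is one block) whose requirement
  is zero after flooring;
* the **winter cluster** is everything else, carrying one level equal to
  the **maximum** monthly requirement in the block.

The maximum is the only aggregation that never undershoots the serum
target in any winter month; with the default calibration it equals the
January (trough-month) requirement. A mean aggregation is available
behind `cluster_plan(..., aggregate = "mean")` for cost-oriented
planning, at the price of undershooting in the deepest winter months.
Under the default calibration the 50 nmol/L mean-bread plan pauses
fortification exactly May–September; the 75 nmol/L plan fortifies all
year.

## Numerical choices and degenerate inputs

* All arithmetic is kept at full double precision; rounding to one
  decimal is a display concern, and CSV exports carry 6 significant
  digits.
* Flooring (`max(0, ·)`) is applied per month *before* clustering.
* Zero carrier consumption (the juice 5th percentile) makes the
  fortification level undefined. Single-cell calls raise an error
  directing the user to a nonzero-consumption scenario; the scenario grid
  instead flags the cell infeasible so one empty cell cannot fail an
  81-cell run; intake multipliers return `NA` with an `undefined` marker,
  since a ratio with a zero denominator carries no information.
* Safety flags use strict inequalities: a total intake of exactly
  100 μg/day or a serum value of exactly 500 nmol/L does not flag,
  because the thresholds are stated as limits, not exceedances.
* Amplitude calibration refuses anchors a quarter-period from the trough,
  where the cosine is zero and the amplitude unidentifiable.
* Ties in the summer-cluster search (two equally long zero runs) resolve
  to the first run in January-first order; with realistic seasonal
  baselines ties do not occur.

## Design decisions

* **Winter level = max, not mean** (see above; the published "during
  winter" level equals the trough-month value, consistent with max).
* **Two clusters only.** The model contrasts one summer pause with one
  winter level; arbitrary k-clusterings are out of scope.
* **Gender selection as max/min** rather than hard-coded "men"/"women"
  labels, so custom carriers inherit the convention automatically.
* **Supplements enter as a scenario-independent mean** (0.3 μg/day),
  configurable but without percentiles.
* **The conversion factor is a parameter**, not re-derived from the
  underlying fortification trials; sensitivity to lower literature values
  (0.5–1.5 nmol/L per μg) is explored by overriding `conversion_factor`
  in the configuration.

## Problem sizes

Default analyses are small and deterministic: the constant grid has
3 carriers × 3 carrier percentiles × 3 intake percentiles × 3 targets =
81 cells, the seasonal grid 54 cells × 12 months, and the property-style
tests draw 1 000 random parameter sets for the formula-equivalence checks
and a few dozen for monotonicity and calibration round-trips. A full
pipeline run completes in well under a second.

## Limitations

* Average-population model: no individual-level prediction and no
  population fraction above a threshold; the envelopes are scenario
  bounds, not confidence intervals.
* Serum-target plans inherit all uncertainty in $c_f$, which the
  literature places anywhere between 0.5 and 2.32 nmol/L per μg/day.
* The cosine baseline is a stand-in; conclusions about specific months
  sharpen only with observed monthly baselines.
* Risk envelopes at the dietary-intake extremes rest on placeholder
  percentiles (see above) and are reported as orderings.
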