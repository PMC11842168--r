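---
title: "Simulating smolt migration through lakes as a correlated random walk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating smolt migration through lakes as a correlated random walk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Downstream-migrating Atlantic salmon smolts are strongly rheotactic in
rivers, but lakes offer little directional current. A standing hypothesis in
movement ecology is that smolts entering a lake fall back on a *random
search*: locally straight swimming with small random heading changes, until
the outflowing river is encountered by chance. `lakewalk` implements that
hypothesis as a correlated random walk (CRW) bounded by the shoreline and
asks how basin shape and the two behavioral parameters of the walk — step
length and turning-angle dispersion — shape migration success, distance
travelled, and passage time.

A path is a sequence of fixed-length steps of length $L$ (meters). After
each step the heading changes by a turning angle drawn from
$\mathcal{N}(\mu = 0, \sigma)$ (degrees, untruncated), so the walk is
directionally persistent over scales of order $L \cdot 2/\sigma_{rad}^2$ but
diffusive beyond them. The first step is treated like every later one: a
turn is drawn around the initial bearing, which represents the direction at
which the inflowing river intercepts the lake.

**Boundary collisions.** A proposed step whose endpoint would leave the lake
polygon (or, for non-convex shorelines, whose swept segment would cross it)
is rejected and the turn redrawn with an inflated standard deviation

$$\sigma_k = \sigma \, (1 + c\,k^{e}), \qquad c = 0.1,\; e = 2,$$

where $k$ counts the failed attempts for the current step ($k = 0$ on the
first draw). The inflation frees the walker from the shoreline without
biasing it in open water; $k$ resets to zero once a step is accepted, so the
correlation structure of the walk is preserved away from shore. The typeset
source of this rule is ambiguous between $\sigma(1 + 0.1k^2)$ and
$\sigma\left((1 + 0.1k)\right)^2$-style readings; the first is the default
here and both $c$ and $e$ are exposed (`collision_coeff`,
`collision_exponent`) so either reading can be run. A retry ceiling
(`max_collision_retries`, default 100 redraws per step) guarantees
termination; paths that exhaust it end as `failure_retries` and are counted
separately (in practice the inflation rule makes them vanishingly rare).

**Termination.** A walk succeeds when it enters the circular *capture
region* at the outlet, fails with `failure_cap` when it reaches the path
cap of `max_path_length` meters (at most
$\lfloor \texttt{max\_path\_length}/L \rfloor$ steps, so every path with
the same step length has the same maximum length). Distance travelled is
exactly $L \times$ steps; passage time converts distance at a fixed swim
speed of 0.17 m s$^{-1}$, assuming continuous swimming 24 h per day
(14,688 m per simulated day).

## The capture region, and an ambiguity that matters

The outlet is modelled as a circle centered on the shoreline, specified by a
perimeter target (440 m for the hypothetical basins; 31/29/50/200/73 m for
the five real lakes). Two conventions for that number circulate:

* **exposed arc** (the default, `capture_sizing = "exposed_arc"`): the
  target is the arc length of the circle lying *inside* the lake; the radius
  is solved numerically by bisection on the measured inside-arc length
  (about $440/\pi \approx 140$ m on a straight shoreline);
* **circumference** (`capture_sizing = "circumference"`): the target is the
  full circle circumference, so $r = 440/2\pi \approx 70$ m.

Independently, entry can be detected on the **swept segment** of each
proposed step (default, `capture_mode = "segment"`; entering counts even if
the step's endpoint exits again, and a step crossing the region succeeds
even if its endpoint would leave the lake, since the region straddles the
shoreline) or only at **step endpoints** (`"point"`), and either check can
be applied before or after the shoreline bounce (`"accepted_segment"`,
`"accepted_point"`). These choices are consequential: with the default
(exposed-arc, segment) reading, success pooled over $\sigma$ *rises*
monotonically with step length on the hypothetical basins, whereas the
published surfaces we emulate peak near 100 m and decline markedly at
200 m; that decline emerges only under the smaller circumference radius
combined with endpoint or bounce-first detection, which lets 200-m steps
overshoot a ~140-m-wide target. No single combination reproduces every
published value, so the package ships the default reading and exposes the
alternatives as explicit switches rather than silently picking per-quantity
winners. The consequences are visible in the acceptance checks: the
50–100 m cells, the terminal-vs-lateral contrast, and the distance contrast
reproduce closely under the defaults, while the 200-m cells and the largest
$\sigma$ contrasts do not.

## The hypothetical basins

Four single-ring basins are generated analytically (no GIS dependency), all
with a 440-m capture target and, for (a)–(c), start and capture 5.5 km
apart:

* **circular** (`make_circular_basin()`): area 25.0 km²; the polygon radius
  is solved so the *discretized* 256-gon hits the area exactly; 5.5 km is
  nearly a diameter, so start and outlet are almost antipodal.
* **elliptical** (`make_elliptical_basin()`): area 22.1 km², aspect 2:1 by
  default (the aspect is not published; 2:1 is read qualitatively from the
  basin sketches and exposed as an argument). The start keeps the circle's
  parametric angle; the capture is slid along the boundary until the 5.5-km
  separation holds, since equal parametric angles cannot achieve it on an
  ellipse.
* **rounded-rectangular, lateral and terminal**
  (`make_rectangular_basin()`): area 27.8 km², corner radius equal to half
  the short side (so the short ends are semicircular caps). The published
  constraints — area 27.8 km² and an 11.3-km terminal start-to-end
  separation — jointly fix the outer dimensions (11.3 × 2.59 km, aspect
  ≈ 4.4:1), which is why the length is derived from those two numbers
  rather than from a fixed 4:1 aspect; passing `aspect` overrides this.
  The lateral variant puts start and capture on one long side 5.5 km
  apart; the terminal variant puts them at the two cap apexes.

Initial bearings for hypothetical basins are the inward normal at the start
(a neutral, symmetric choice; only the real lakes have published river
bearings). All basins are uniformly rescaled after discretization so the
polygon area matches the target exactly, making the ±0.2% area contract
hold by construction. One published statement gives all basins a common
24.3 km² area while the per-shape figures give 25.0/22.1/27.8; the
per-shape values are the default and
`make_hypothetical_basins(common_area_km2 = 24.3)` switches to the common
area.

## Real-lake fixtures

The five real study lakes (Achonachie, Meig, Garve, Lomond, Bassenthwaite)
are shipped as *synthetic approximations*: smooth star-shaped harmonic
outlines with roughly the right elongation and start/outlet placement, not
digitized shorelines. They are flagged `approximate = TRUE`, rescaled at
load to the published surface areas (0.69/0.45/1.83/71/5.1 km²), and given
the published capture perimeters and path caps (75/75/55.8/75/30.4 km — the
two sub-75 caps are the published values, kept verbatim even though they
are arithmetically inconsistent with swim speed × the published longest
successful passage times; `max_path_length_for_lake()` exposes the formula
for sensitivity runs). Quantitative results on these fixtures are
illustrative only; qualitative patterns (near-100% simulated success on the
two small Conon-catchment lakes, low success on Lomond) do reproduce.

## Synthetic telemetry

`generate_telemetry()` emulates per-fish acoustic-telemetry summaries:
Bernoulli success and, for successes, lognormal passage durations
moment-matched to a requested mean/SD. The lognormal reproduces the
strongly right-skewed, SD-of-order-mean durations seen in tracked smolts
while staying strictly positive. `lake_telemetry()` presets the published
per-lake rates and durations. What these records do *not* emulate: arrival
seasonality, detection failures, tag loss, or predation-censored fish — so
agreement of simulations with synthetic telemetry shows internal
consistency of the pipeline, not fidelity to any particular field dataset.

## Statistics

The statistical layer mirrors standard practice for simulation studies of
this kind and leans on base R for the canonical pieces:

* `fit_success_glm()`: logit-link binomial GLM on per-path binary outcomes
  (likelihood-equivalent to aggregated proportions), with odds ratios
  $e^\beta$ and Wald intervals. The default interval level is 95%;
  `ci_level = 0.975` reproduces reports that quote 97.5% intervals (most
  likely a typo for 95%, so the unusual level is opt-in rather than
  default). Complete separation is flagged and intervals suppressed.
* `lrt()` / `select_success_glm()`: likelihood-ratio tests between nested
  fits and backward elimination at $\alpha = 0.05$, stopping when nothing
  further can be dropped.
* `chisq_success()`: Pearson chi-squared on success/failure count tables,
  without continuity correction by default (multi-group usage; Yates is
  opt-in for 2×2).
* `kruskal_dunn()`: tie-corrected Kruskal–Wallis plus hand-computed Dunn
  pairwise Z statistics on the shared ranks, Holm–Bonferroni adjusted
  (`stats::p.adjust`).
* `compare_to_telemetry()`: per-cell exact binomial tests of simulated
  success against the empirical rate, plus interval-coverage flags for the
  rate (Clopper–Pearson) and mean passage time (t-interval).

## Reproducibility and numerics

The simulation engine uses its own counter-based RNG (splitmix64 with
Box–Muller normals); path $i$ of an ensemble uses substream
$\mathrm{mix}(s, i)$ of the ensemble seed $s$, so ensembles are
bit-identical across platforms, independent of R's RNG state, and stable
under extension (growing $n$ or taking `first_stream` windows never
changes earlier paths). Grid cells derive their seeds from a stable string
hash of (global seed, basin, step length, $\sigma$), so editing a design
never perturbs the other cells. `reproduce()` writes cells/paths CSVs, the
basin GeoJSONs, and a manifest with the seed and file checksums; identical
seeds give byte-identical CSVs.

Numerical details worth knowing: polygons are implicitly closed,
counter-clockwise, validated non-self-intersecting; containment is even-odd
with the boundary counted inside (so exact boundary landings never escape);
capture sizing bisects on an arc-length measurement that refines each
inside/outside transition by angle bisection (achieved arc within 0.5% of
target, inside the 1% contract); bearings are degrees clockwise from grid
north and turning angles signed degrees (positive clockwise); $\sigma = 0$
is an exact degenerate case (no noise at all), which gives the analytic
straight-line path in an unobstructed corridor.

## Problem sizes

The package's own test and reproduction scale is the full published design:
80 cells × 200 paths (16,000 paths, ≈ 8 s on one CPU) for the hypothetical
grid and 45 cells × 200 paths (9,000 paths) for the real-lake grid. A
smoke scale (20 paths per cell) is bundled for quick checks
(`reproduce(..., scale = "smoke")`).

## Worked example

```{r, eval = FALSE}
library(lakewalk)

basins <- make_hypothetical_basins()
design <- hypothetical_design(n_per_cell = 200, seed = 42, basins = basins)
grid <- run_grid(design)

# success pooled over sigma at each step length
pooled_success_rate(grid, "circular", step_lengths = 100)

# the shape contrast at the tightest turning distribution
pooled_success_rate(grid, "circular", turn_sds = 2) -
  pooled_success_rate(grid, "rectangular_lateral", turn_sds = 2)

# model the surface
fit <- fit_success_glm(grid$records,
                       success ~ basin + step_length + turn_sd)
fit$odds_ratios
```

## Known limitations

* The elliptical and rectangular proportions, and the exact angular
  placement of start/outlet on the hypothetical basins, are not published;
  the defaults are figure-level reconstructions and the success surfaces
  are sensitive to them at the several-percentage-point level.
* The capture-region ambiguity described above dominates the behavior at
  long step lengths; results at 200-m steps depend qualitatively on the
  chosen reading.
* Real-lake fixtures are synthetic stand-ins; no numeric conclusion should
  be drawn from them beyond qualitative ordering.
* The walk has no behavior beyond the CRW: no flow-cue-directed navigation
  near the outlet, no Lévy or biased walks, no time-varying speed, no
  diel activity cycle.
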