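---
title: "Polynomial surface fitting of scattered pollutant observations: models, protocol and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polynomial surface fitting of scattered pollutant observations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opfit)
```

## The problem

Ground monitoring of fine particulate matter (PM2.5) produces scattered
point observations: a few hundred city-level concentrations over a region
spanning tens of degrees of longitude and latitude. Exposure assessment
and air-quality work need the field everywhere, so the scattered values
must be interpolated onto a grid. `opfit` implements a global polynomial
surface fit for this task and benchmarks it against the two interpolators
most widely used in atmospheric applications: Cressman objective analysis
and ordinary kriging.

## The surface model

The fitted surface is a tensor product of Chebyshev polynomials of the
first kind,

$$\hat f(x, y) \;=\; \sum_{i=0}^{s} \sum_{j=0}^{k}
  a_{ij}\, T_i(x')\, T_j(y'),
\qquad T_m(t) = \cos(m \arccos t),$$

where $x', y'$ are longitude and latitude affinely mapped onto the
reference square $[-1, 1]^2$ over a rectangular domain (by default the
bounding box of the training stations; `map_to_reference()`). The
coefficients $a_{ij}$ minimize the sum of squared residuals at the
stations. The orders $s$ and $k$ — the maximum polynomial degrees in the
longitude and latitude directions — are the model's only tuning
parameters; they are capped at 10 by default because a few hundred
stations cannot constrain many more than $(10+1)^2$ coefficients.

Three numerical choices matter here and are deliberate:

* **Basis.** The monomial tensor basis $x'^i y'^j$ spans the same function
  space but its design matrix becomes numerically unusable near order 10;
  the Chebyshev basis keeps columns near-orthogonal over the reference
  square. The tests assert that both bases give identical fitted values on
  well-conditioned instances, which pins down the function space
  independently of the basis.
* **Solver.** The least-squares system is solved by singular value
  decomposition with a relative cutoff of `1e-10`. On rank-deficient
  designs (collinear stations, extreme orders) the minimum-norm solution
  is returned with a warning rather than an error, and the retained rank
  and condition number are kept on the fitted object for inspection.
* **Minimum data.** A fit demands at least $(s+1)(k+1)$ stations. Below
  that the system is underdetermined and the error message names the
  required minimum.

Raw polynomial values can be negative in clean-air regions; error metrics
always use the raw values, and flooring at zero (`clip_zero = TRUE`) is
available for presentation output only.

Coordinates are treated as planar degrees throughout (plate carrée). At
the scale of the default study zone this distorts east–west distances by
up to ~25% relative to great-circle distances, but it keeps every
distance-scaled parameter (influence radii, variogram range) in the
degree units in which such parameters are conventionally quoted for this
kind of regional analysis.

## The comparators

**Cressman objective analysis** estimates each grid node as a weighted
mean of the stations inside an influence radius $R$, with the classical
kernel $w = (R^2 - d^2)/(R^2 + d^2)$. The radius is adaptive: it starts at
4° and grows in 0.1° steps until at least five stations lie strictly
inside it (equivalently, the final radius is the smallest value on that
ladder strictly exceeding the fifth-nearest station distance — the
implementation uses this closed form, which is exactly the grow-loop's
fixed point). A single weighted pass is performed, with no
successive-correction iterations, and a hard radius cap (default: the
station bounding-box diagonal) turns pathological isolation into an error
instead of an unbounded search. Estimates are convex combinations of
in-range observations, so they can never leave the local data envelope —
nor track any structure finer than the radius.

**Ordinary kriging** uses a fixed spherical semivariogram
($\gamma(h) = c\,(1.5 h/a - 0.5 (h/a)^3)$ up to the range $a$, constant
beyond) with range 10°, sill 1 and nugget 0, and solves the standard
$(n+1)$-equation system per query point (all stations in every system —
no search neighborhood, appropriate for a couple of hundred stations).
With zero nugget the predictor honors each observation exactly at its own
location. The nominal sill has no effect on the estimates — only on the
kriging variance — because rescaling the semivariogram rescales the
Lagrange multiplier but not the weights; a test asserts this invariance,
which also disposes of the question of the sill's units. No empirical
variogram is fitted: the fixed model is part of the method definition
being compared.

## The evaluation protocol

Two designs are implemented:

* **Twin experiments.** A prescribed truth field is sampled at synthetic
  stations (optionally with observation noise), each interpolator
  reconstructs the field on a grid, and MAE/RMSE against the truth are
  computed over all grid nodes, together with the composition of absolute
  errors over the bins $[0,5), [5,10), [10,15), [15,20), [20,\infty)$
  µg·m⁻³.
* **Hold-out cross-validation.** Eight folds each hold out 15 stations
  ("set A") and train on the rest ("set B"); fold MAEs are averaged.
  "Well distributed" validation sets are operationalized by seeded
  k-means: stations are partitioned into 15 spatial clusters and each
  fold draws one station per cluster. When every cluster has at least 8
  members the draws are made without replacement across folds, so the
  eight validation sets are pairwise disjoint (always feasible at 225
  stations); otherwise the sampler falls back to independent per-fold
  draws and says so. Everything is a deterministic function of the seed.

The **order search** runs this cross-validation for the surface fit at
every $(s,k) \in \{1,\dots,10\}^2$. Cells infeasible on any training fold
(fewer stations than coefficients) are reported as missing rather than
silently skipped or set to infinity, so the MAE surface remains honest.
Ties at the minimum prefer the smaller $s+k$, then the smaller $s$
(parsimony). The characteristic result is U-shaped: low orders underfit
the contamination centers, high orders fit noise through sparse data and
degrade catastrophically — on the default synthetic conditions the
diagonal of the MAE matrix rises several-fold between its interior
minimum and $s=k=10$.

## What the synthetic generator emulates — and what it does not

The package carries its own truth-field generator so that the whole
pipeline is testable without any external data. A `blob_field` is a
constant background plus Gaussian bumps; two presets encode the canonical
bimodal pollution geometries: `ie1_preset()` (heavy contamination
northwest, clean pocket southeast — the most common continental winter
pattern) and `ie2_preset()` (heavy southeast, clean southwest — a
spring/autumn pattern). Stations are placed by seeded jittered-grid
sampling: one uniform draw inside each cell of a near-square tiling,
giving an irregular but space-covering network with no duplicate
coordinates.

Default parameter choices, made once:

* **Domain** lon 97–123°E, lat 18–38°N — a rectangle approximating
  central/southern China, so that the degree-scaled method parameters
  (4° radius, 10° range) have realistic reach. 225 stations matches a
  national city-level network over such a zone.
* **Magnitudes**: background 60, amplitudes +70/−50 µg·m⁻³ — field values
  span roughly 10–130 µg·m⁻³, the range of daily PM2.5 maps, and stay
  nonnegative.
* **Center geometry**: centers at 30%/70% of the box extents with width
  4° (≈ 8° diameter at half maximum). This gives each contamination
  episode a distinct regional footprint: structure broad enough for a
  degree-5 surface to represent, yet fine enough that averaging over a 4°
  influence radius visibly blurs it. This is the regime in which the
  three methods genuinely differ — a pocket-free, very broad field makes
  all three nearly indistinguishable and is not representative of
  observed episode maps.
* **Observation noise** sd 5 µg·m⁻³ for method-comparison runs, a
  realistic city-level daily measurement-plus-representativeness error.

With these conditions the twin experiments reproduce the expected method
ordering — surface fit best, kriging second, Cressman last on mean grid
MAE — as an *ordering*, with each method failing for its characteristic
reason: zero-nugget kriging reproduces observation noise exactly at
stations, Cressman blurs the contamination centers, and the global
polynomial filters noise (36 coefficients from 225 observations) while
representing the large-scale structure.

The generator does **not** emulate real spatiotemporal PM2.5 dynamics: no
meteorology, no terrain channeling, no east-dense/west-sparse station
inhomogeneity, no seasonal trend, and the truth fields are exactly smooth
Gaussian mixtures. Passing tests therefore demonstrate the correctness of
the machinery and the qualitative behavior of the methods on
bimodal-episode geometries — not quantitative error levels on any real
monitoring day.

## Problem sizes

The shipped tests and the acceptance script use a 0.5° evaluation grid
(2173 nodes), 20 twin-experiment replicates per geometry, and a full
10×10 order search on one 225-station network — sizes at which every
qualitative result above is stable across seeds while a complete run
stays comfortably interactive.

## Known limitations

* Planar-degree geometry; no spherical basis or great-circle distances.
* The surface fit is global and unregularized: it can oscillate outside
  the station bounding box and should not be extrapolated.
* Only the spherical variogram family and single-pass Cressman scheme are
  provided, since they are the comparison targets — this is not a
  general-purpose geostatistics toolkit.
* Negative estimates are possible from both the surface fit and kriging;
  flooring is cosmetic and never used in scoring.

## A worked example

```{r example, eval = FALSE}
field <- ie1_preset()
stations <- sample_stations(field, n = 225, seed = 1, noise_sd = 5)
surface <- fit_surface(stations, s = 5, k = 5)

grid <- grid_spec(field$domain, d_lon = 0.5, d_lat = 0.5)
pts <- grid_points(grid)
truth <- evaluate_field(field, pts$lon, pts$lat)

c(opf = mae(evaluate_surface(surface, pts$lon, pts$lat), truth),
  kriging = mae(ordinary_kriging(stations, pts$lon, pts$lat)$values, truth),
  cressman = mae(cressman_interpolate(stations, pts$lon, pts$lat)$values,
                 truth))

plan <- make_cv_folds(stations, n_folds = 8, holdout_size = 15, seed = 1)
order_search(stations, plan, max_order = 10)
```
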