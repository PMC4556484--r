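---
title: "Locating dispersal origins from dated site records: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating dispersal origins from dated site records: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ricewave)
```

## The inference problem

An archaeobotanical database records dated phases at sites where a crop —
here, rice — has been identified. Each record is a *terminus ante quem* for
local arrival: a site may have been occupied, sampled or dated long after
cultivation first reached it, but (dating errors aside) not before. The
question the package answers is geographic: from which origin point or
points would an expanding wave of cultivation best explain the observed
ages?

Three modelling commitments follow from the one-sided nature of the
evidence.

1. **Distances are cost distances.** Straight-line distance ignores coasts,
   deserts and cold uplands that a spreading practice must negotiate. We
   compute shortest-path distances on a masked equal-area grid with a Fast
   Marching solver — the simplest "near-geography-free" cost model: no
   friction heterogeneity, only passable and impassable cells.
2. **The regression targets an envelope, not a mean.** Because observed ages
   under-estimate first arrival, the informative sites at a given distance
   are the *oldest* ones. We fit a quantile regression positioned so a small
   fraction `q_exceed` (default 0.10) of sites lies above (older than) the
   curve.
3. **The age–distance law is a power law.** Crops under domestication spread
   slowly at first and accelerate; a straight line in log-log space,
   `age = A · distance^b` with `b < 0`, captures that changing rate with two
   parameters.

## Domain model

All rasters live on a Lambert Azimuthal Equal Area grid (spherical forward
and inverse projection, authalic radius 6371.0088 km), so each cell covers
`cell_size²` km² and areas are obtained by cell counting. Cells are
cell-centre registered; site coordinates snap to the nearest centre.

A land cell is traversable unless

* its annual growing degree-day total — `Σ_months max(0, T_m − base) ×
  days-in-month` on a 365-day calendar — is below `dd_threshold` (default
  2,500 °C·day with base 0 °C, the envelope of rice agronomy); the
  threshold is exclusive: exactly 2,500 is kept; or
* it is mapped as desert.

A sea cell is traversable iff its centre lies within `buffer_km` (default
40 km) of a land-cell centre. Two such buffers meeting bridge a channel of
up to 80 km, which is what connects, e.g., an offshore archipelago to the
mainland; anything wider stays disconnected. The buffer is measured from
*any* land, including cold-masked land, since coastal transport does not
care whether the interior is cultivable; this can leave small traversable
buffer pockets that are unreachable from the main landmass, which is
harmless (they contain no analysis sites in practice and unreachable sites
are flagged).

Candidate origins for the unconstrained search are the nodes of a square
lattice (default spacing 100 km) snapped to cells and intersected with the
traversable set, in row-major order.

## Fast marching

The solver is the standard first-order 4-neighbour upwind discretisation of
the eikonal equation with a binary heap, which guarantees pops in
non-decreasing arrival order. The one-cell update is

* one-sided, `min(t) + h/speed`, when the two upwind directions disagree by
  at least one cell-crossing time, and
* the quadratic solve `(t_h+t_v)/2 + ½·sqrt(2(h/speed)² − (t_h−t_v)²)`
  otherwise.

Axis-aligned propagation is exact; oblique propagation over-estimates the
true geodesic by a bounded stencil error (provably at most √2, empirically
a few percent in the far field, shrinking under grid refinement). The test
suite brackets every arrival field between 8-connected and 4-connected
Dijkstra oracles.

Competing fronts: each origin runs as a unit-speed front in its own time
scale, and the fields are combined as the pointwise minimum of
`start_offset + distance / speed_ratio`. With homogeneous friction this
minimum is exactly the multi-source competitive solution, so no joint run
is needed; the claiming source is the argmin, ties resolved to the lowest
source index. All start offsets default to zero (simultaneous starts);
effective distances are expressed in the first process's distance units so
multi-origin regressions keep a single covariate.

## Quantile fit and model selection

The envelope fit minimises the check loss `ρ_τ(r) = r(τ − 1[r<0])` of
`ln(age)` on `ln(distance)` at `τ = 1 − q_exceed`, via the Barrodale–
Roberts simplex (an exact LP solution through at least two data points).
Distances below one cell size are clamped to the cell size before the log
transform — a site sitting on the origin cell otherwise has no defined
log-distance; whether to clamp or drop such sites is a genuine open choice,
and clamping keeps `n` stable across candidate origins.

The fit's likelihood is the asymmetric-Laplace form with plug-in scale,

```
loglik = n [ ln(τ(1−τ)) − 1 − ln(mean check loss) ],
```

which is symmetric in τ ↔ 1−τ, and model quality is the small-sample
corrected AIC, `AICc = −2·loglik + 2K + 2K(K+1)/(n−K−1)`. Parameter counts:
two regression coefficients plus one scale (`K = 3`), plus one per *free*
speed ratio; searched origin coordinates are deliberately not counted, so a
searched single origin also has `K = 3`. A perfectly collinear (zero-loss)
configuration is flagged and given a `+Inf` log-likelihood sentinel rather
than a fabricated finite value.

Free speed ratios are estimated inside `[0.01, 20]` by maximising the AL
log-likelihood: nine log-spaced starts per ratio, golden-section (one
ratio) or Nelder–Mead on a logistic box transform (two or more), then a
snap-to-bound step — if a bound fits within 1e−9 of the interior optimum
the estimate is reported *at* the bound and flagged, since a vanishing or
dominating front leaves the likelihood flat over a ratio plateau. The whole
procedure is deterministic.

Model comparison: `Δ = AICc − min(AICc)`, relative likelihood `exp(−Δ/2)`,
Akaike weights normalised to one; models must share the same site set. A
log-likelihood support interval of 2 corresponds to Δ = 4 at equal `K`,
which is the default cutoff for origin support regions.

## Origin search and kriging

Each candidate gridpoint is scored as a single origin (fast march →
distances → envelope fit → AICc). The AICc values are interpolated to the
full raster by ordinary kriging — equivalently, simple kriging about the
GLS-estimated constant mean — with an exponential covariance whose range
and sill are fitted by profile maximum likelihood (golden-section on log
range; a moment-based fallback with a warning if the likelihood is
degenerate). The nugget defaults to zero, so the surface honours the
observed gridpoint values exactly; interpolation happens on the AICc scale
*first*, and the best observed value is subtracted afterwards to give the
Δ surface. Gridpoints with non-finite fits (no reachable sites) are
excluded with a message.

Two honest findings about support regions under the default synthetic
conditions (330 sites, moderate noise), both recorded by the package's own
tests rather than assumed:

* the AICc surface is extremely sharp — moving the origin one lattice step
  changes mean check loss by a fraction of a percent, but multiplied by
  `n = 330` that is several AIC units — so the Δ ≤ 4 region typically spans
  only a handful of cells around the best gridpoint;
* consequently, in dual-origin worlds the region concentrates at or between
  the true origins and essentially never covers both of them, and even in
  single-origin worlds an off-lattice origin falls outside the region in a
  substantial minority of runs. A single-origin search on multi-origin data
  localises a compromise point very precisely; it does not bound the set of
  true origins. Explicit multi-origin hypotheses, compared by AICc, are the
  tool for that question.

## The Monte Carlo index benchmark

The benchmark asks which fitness index — Pearson r, Spearman ρ, adjusted
R², OLS-AIC, or quantile-AIC — most reliably picks a known dispersal source
out of an 11×11 candidate grid overlaid on 500 synthetic points. Ages
follow a linear (`age = 1 − d/2`) or power-law (`age = 10000·d^−0.3`,
distances clamped at 0.05 on the unit square) rule; the constants are the
package's own choice, made once, so that ages stay positive over the
domain. Noise is one-sided Rayleigh underestimation: observed age =
`true × max(0, 1 − ε)`, `ε ~ Rayleigh(σ)` (floored at 1e−3 of the true age
in the log-log scenario so logarithms stay defined), and by default each
point is also displaced toward the origin by an independent Rayleigh
fraction, modelling underestimated travel distances. σ spans 0.001–1:
at 0.001 observations sit essentially on the rule; at 1 the noise is of the
order of the signal.

Selections use |r| for the correlations (dispersal correlations are
negative in BP units), max for adjusted R², min for the AICs. For simple
regressions adjusted-R² selection and OLS-AIC selection are the same
monotone function of the residual sum of squares, and the package computes
both independently and asserts their identity per iteration. Iterations
are binned by the realized |Pearson| correlation between observed age and
true-origin distance in the scenario's regression space (per-iteration
binning; a per-σ convention would be equally defensible).

Measured behaviour (acceptance script, seed 1, desk scale): quantile-AIC
dominates the OLS family at moderate noise and stays near-perfect at low
noise, but in the lowest correlation bin (|r| < 0.1) its success rate is
about 7% — far above the 0.8% chance level, far below certainty. We found
no reading of the one-sided noise model that decouples envelope
recoverability from realized correlation: both are driven by the same
signal-to-noise ratio, so selection power necessarily decays with |r|.
Claims of near-certain source recovery at correlations near 0.05 should
therefore be read against the exact noise mechanism that produced them.

## The synthetic toy world

`make_toy_domain()` builds a continental landmass with a sea margin, an
optional offshore island separated by a (default 70 km, hence bridged)
channel, a desert patch, and a north–south temperature gradient whose
northern rows fall below the degree-day threshold — every mask type is
exercised. `simulate_site_table()` samples sites uniformly over traversable
cells, assigns true ages by the power-law clock on effective distance from
the configured origins (defaults: two origins ~1500 km apart, speed ratios
{1, 0.78}), applies multiplicative Rayleigh underestimation (σ = 0.15,
floored at 5% of true age), and synthesises calendar phase intervals of
random 100–400 year half-width around each observed age. σ = 0.15 was
chosen a priori so that realized age–distance correlations land in the
0.5–0.8 band typical of published continental-scale dispersal datasets.

What the generator does *not* emulate: spatially clustered site discovery,
radiocarbon calibration structure, multi-phase occupation histories,
coastline change, and heterogeneous travel costs. Tests passing on these
worlds show the estimators recover the truth *under the model's own
assumptions*; they do not validate the assumptions against real data.

Default problem sizes (60×90 cells of 40 km, 330 sites, 100 km search
lattice, ten noise levels × 200 iterations in the benchmark) are desk-scale
choices: large enough for stable quantile fits, small enough that the full
test suite and the acceptance run complete in minutes on one CPU. The full
ladder (fifty noise levels × 1000 iterations) is available through
`bench_config()`.

## Numerical conventions and degenerate inputs

* Calendar years are signed, BC negative, astronomical numbering;
  `median_age = 1950 − (start + end)/2` years BP. Phase order is normalised
  on read.
* Unreachable sites carry an `Inf`/`NA` sentinel and are excluded from fits
  with a logged count; a site snapped to a masked cell falls back to the
  best traversable cell within one cell, else is flagged unreachable.
* Raster I/O uses ESRI ASCII grids (plain text; nodata honoured). The
  projection centre is not part of that format and must accompany the file.
* KML/KMZ reading is best-effort: placemark coordinates plus a configurable
  `ExtendedData` field-name map; undated placemarks are kept with `NA` ages
  and a warning.
* Ties: competing-front labels resolve to the lowest source index; the
  oldest-phase reduction keeps the first of exactly tied phases.
* Seeds: every stochastic entry point takes an explicit seed
  (`toy_world_config(seed=)`, `bench_config(seed=)`); regenerating with the
  same seed reproduces tables bit-for-bit.

## Limitations

* First-order FMM only; no second-order stencils, anisotropy, or
  heterogeneous friction surfaces — the cost model is passable/impassable.
* No radiocarbon calibration or chronological modelling; ages are taken as
  given phase midpoints.
* No standard errors or confidence intervals for the quantile coefficients;
  inference is by information criteria only.
* The unconstrained search considers single origins; multi-origin support
  must be assessed through explicit hypotheses.
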