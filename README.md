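# ricewave

Spatially explicit inference of dispersal origins from dated archaeological
site records, built around the case of rice cultivation spreading across
Asia.

Archaeobotanical databases record *where* and *when* a crop has been found;
they do not record where its cultivation began. `ricewave` turns the first
kind of evidence into the second. Given a table of dated site phases and an
ecological modelling domain, it asks: from which point (or points) would a
spreading wave of cultivation best explain the dates we observe?

The pipeline:

1. **Domain building** — an equal-area raster (Lambert Azimuthal Equal Area)
   in which land is traversable unless it is too cold for the crop (annual
   growing degree-days below 2,500) or desert; sea is traversable only
   within a 40 km coastal buffer, so islands up to 80 km offshore connect to
   the mainland.
2. **Cost distances** — a first-order Fast Marching solver for the eikonal
   equation |∇T|·F = 1 computes, for every cell, the length of the
   computational shortest path from a putative origin, negotiating the
   masked regions. Multiple competing origins run as fronts with relative
   speed ratios; each cell is claimed by the first front to arrive, and
   effective distances are expressed in the first process's units.
3. **Quantile envelope regression** — ages (years BP) are regressed on cost
   distance in log-log space, but to an upper envelope rather than the mean:
   the fitted power law `age = A · distance^b` leaves a fraction
   `q_exceed = 0.10` of sites older than the curve, so it tracks earliest
   arrivals rather than average (re)occupation. The fit minimises the check
   loss at τ = 1 − q_exceed (exact linear-programming solution).
4. **Model selection** — each fit gets an asymmetric-Laplace log-likelihood
   `n[ln(τ(1−τ)) − 1 − ln(mean check loss)]` and a small-sample corrected
   AIC, `AICc = −2ℓ + 2K + 2K(K+1)/(n−K−1)`. Hypotheses (one, two or three
   origins; free speed ratios estimated in [0.01, 20]) are compared by ΔAICc,
   relative likelihoods `exp(−Δ/2)` and Akaike weights.
5. **Unconstrained origin search** — every node of a 100 km lattice over the
   domain is scored as a single origin; ordinary kriging (exponential
   covariance, maximum-likelihood parameters) interpolates the AICc values
   into a ΔAIC surface whose Δ ≤ 4 contour bounds the supported origin
   region.
6. **Monte Carlo index benchmark** — a geometry-free experiment measuring
   how often Pearson/Spearman correlations, adjusted R², OLS-AIC and
   quantile-AIC fitness indices recover a known source from noisy synthetic
   datasets under one-sided Rayleigh underestimation noise.
7. **Synthetic worlds** — a toy-world generator emits raster layers and site
   tables with known truth (origins, speed ratios, power-law clock), so the
   whole pipeline runs and is tested without any external data.

## Worked example

A dual-origin synthetic world (150 sites plus wild-status decoys), reduced
to its analysis set and fitted against single- and dual-origin hypotheses:

```r
library(ricewave)

cfg  <- toy_world_config(seed = 42, n_rows = 40, n_cols = 60,
                         n_sites = 150, wild_fraction = 0.1)
sim   <- simulate_site_table(cfg)
sites <- select_analysis_set(sim$sites, sim$world$domain)
nrow(sites)
#> [1] 147

org    <- sim$world$origins
dual   <- dispersal_hypothesis("dual-origin",
            tibble::tibble(lon = org$lon, lat = org$lat,
                           speed_ratio = c(1, NA)))
single <- dispersal_hypothesis("single-origin",
            tibble::tibble(lon = org$lon[1], lat = org$lat[1]))
fd <- fit_hypothesis(dual,   sim$world$domain, sites)
fs <- fit_hypothesis(single, sim$world$domain, sites)
fd
#> <hypothesis_fit> dual-origin: ratios {1, 0.9553}
#> <quantile_fit> age = 19110.8883 * distance^-0.215552  (q_exceed = 0.1)
#>   n = 147, K = 4, loglik = 90.8373, AICc = -173.3929

compare_models(list(fd, fs))
#>   model          params      n     K loglik    aicc   delta rel_likelihood akaike_weight
#> 1 dual-origin    1, 0.9553 147     4  90.8   -173.4     0         1              1
#> 2 single-origin  1         147     3  14.3    -22.4   151.0       1.62e-33       1.62e-33
```

The dual-origin model recovers a power law close to the generating clock
(`A = 20346.7`, `b = -0.210`) and a second-front speed ratio near the
generating value, and it out-weighs the single-origin alternative by a ΔAICc
of 151 — essentially all Akaike weight. Sites older than the fitted envelope
are candidate extra origins or mis-dated records:

```r
out <- find_outliers(fd$distances, fd$distances$distance_km, fd$fit)
sum(out$outlier)
#> [1] 16        # ~10% of 147, matching q_exceed
```

`autoplot()` methods draw the domain, arrival fields, ΔAIC surfaces and
benchmark curves; `tidy()`/`glance()` return fit summaries as tibbles.

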