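# odflow

Analysis of point-to-point trip records — taxi pick-ups and drop-offs,
bike-share journeys, any origin/destination point data — as a spatially
embedded directed weighted network, together with a generative mobility
model that reproduces the observed statistics.

Urban trip corpora show a robust two-regime structure: the probability that
a trip leaving zone *i* ends in zone *j* is roughly constant for nearby
zones, and decays with distance as a truncated Lévy law beyond a breakpoint.
`odflow` packages the full analysis chain around that observation, for
researchers in human mobility, spatial epidemiology and transport who need
it reusable and testable:

1. **Gridding** — bin trip endpoints into 100 m × 100 m zones
   (equirectangular projection, half-open cells), keep *high-demand* zones
   (≥ M departures **and** arrivals), compute inter-zone haversine
   distances.
2. **OD network** — the origin–destination count matrix `T[i, j]` with
   in/out degrees `k_in = colSums(T)`, `k_out = rowSums(T)` (conservation
   `sum(k_in) = sum(k_out) = total` asserted), plus displacement statistics
   (500 m bins, local `[0, 1.8)` km / long-range `[1.8, 20)` km / far tail
   fractions).
3. **Degree models** — continuous maximum-likelihood fits of power law,
   power law with exponential cutoff, exponential, stretched exponential
   and log-normal on `[k_min, Inf)`, with KS goodness of fit and Vuong
   likelihood-ratio model selection.
4. **Distance kernel** — from the row-stochastic transition matrix
   `w = T / k_out`, estimate the piecewise law

   ```
   w(d) = 10^c                            d <= R
   w(d) = 10^c (R/d) exp(-beta (d - R))   d >  R
   ```

   (plateau `c` and decay `beta` as density modes of per-pair values; the
   breakpoint `R` by a residual scan over a candidate grid).
5. **OD rank** — eigenvalue spectrum of `w`, stationary distribution
   `P∞ w = P∞` (power iteration + dense cross-check), mean-field PageRank
   approximation `P(q) = q/N + (1-q) k_in/total` and its closed-form optimal
   `q*`.
6. **Mobility simulator** — Monte Carlo trips with origins ∝ `k_out` and
   destinations from the kernel model `w_model = Omega / rowSums(Omega)`
   (`Omega = 1` within `R`, the truncated Lévy factor beyond), plus
   log-binned displacement densities for model/data comparison.
7. **Synthetic generator** — zone layouts, heavy-tailed attractiveness
   weights (exact inverse-CDF and rejection samplers) and kernel-driven trip
   tables in a TLC-like CSV dialect, so the whole pipeline is testable
   without the (non-redistributable, billion-record) reference data.

## Worked example

```r
library(odflow)

# 1. synthetic city: 400 high-demand zones in a 10 km x 10 km plane,
#    trips drawn from the local/long-range kernel (R = 1.8 km, beta = 0.15/km)
layout  <- make_zone_layout("uniform-random", 400, extent = c(10, 10), seed = 42)
weights <- sample_degree_values("powerlaw_cutoff",
                                list(gamma = 1, lambda = 6.086e-6),
                                k_min = 1000, n = 400, seed = 43)
trips   <- generate_trips(layout, weights, kernel_R = 1.8, kernel_beta = 0.15,
                          n_trips = 5e5, seed = 44)

# 2. OD matrix, degrees, displacement statistics
od <- build_od(trips, n_zones = 400)
D  <- zone_distances(layout)
displacement_stats(D[cbind(trips$origin_zone, trips$dest_zone)])

# 3. the distance kernel, estimated back from the empirical transition matrix
W     <- transition_matrix(od)
pairs <- kernel_pairs(W, D, d_min = 0.1, d_max = 8)
scan  <- select_R(pairs, R_grid = seq(0.5, 4, 0.1))
scan$fit

# 4. OD rank: spectrum, stationary distribution, mean-field mixing
od_spectrum(W)
p_inf <- stationary_dist(W)
optimal_q(p_inf, od$k_in, od$total)$q_star
```

Output:

```
od_matrix: 400 zones, 500000 trips, 83467 non-null links
displacements: n = 500000, mean = 3.298 km, max = 13.52 km
  [0, 1.8) km: 27.35%
  [1.8, 20) km: 72.65%
  [20, Inf) km: 0.00%
kernel_fit: R = 1.8 km, c = -2.116 (a = 0.007649), beta = 0.1192 /km
  pairs: 10977 with d <= R, 64531 with d > R
od_spectrum: N = 400, max |lambda| = 1.0000000000, unit multiplicity = 1, strongly connected
optimal mean-field q* = 0.0391 (S = 3.84e-05)
```

Reading the numbers: the breakpoint scan recovers the injected `R = 1.8` km
exactly and the decay rate comes back as `0.119 /km` against the injected
`0.15` — at half a million trips the rare long-range links are still
quantised (a link must receive at least one trip to be observed), which
biases the fitted decay low; the estimate converges as the trip count grows
(the test suite checks a 10-million-trip round trip, and the exact-matrix
route recovers the decay within 10%). The simple unit eigenvalue says the
network is strongly connected, and the small `q*` means the stationary OD
rank is dominated by in-degree popularity with only a ~4% uniform
component.

A YAML-configured pipeline wraps the same stages
(`simulate → grid → build-od → fit-degrees → fit-kernel → odrank →
model-sim → compare`):

```r
run_pipeline(read_pipeline_config("config.yaml"))
```

or from a shell via the thin wrapper `inst/cli/odflow.R`:

```sh
Rscript inst/cli/odflow.R all --config config.yaml --seed 4 --out out/
```

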