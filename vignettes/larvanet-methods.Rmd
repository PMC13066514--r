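---
title: "Methods: biophysical dispersal networks and their genetic comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biophysical dispersal networks and their genetic comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`larvanet` implements a complete larval-dispersal connectivity analysis:
particle simulation on surface currents, dispersal-percentage matrices,
graph metrics on the resulting directed network, and Mantel comparison
against genetic differentiation. This vignette records the model, its
assumptions, the numerical choices, and what the synthetic test bed does
and does not establish.

## The biophysical model

Larvae are modelled as passive tracers of the horizontal surface flow.
There is no vertical movement, wind drift, sub-grid diffusion, behaviour,
or mortality: the simulation measures the *physical potential* for
dispersal, not realized recruitment. Positions are advected by

  dx/dt = u(x, t),

with `u` bilinearly interpolated in space and linearly in time from a
gridded (lon, lat, time) velocity field in m/s. Velocities convert to
angular displacement through a local equirectangular metric (one degree =
111.195 km, scaled by cos(latitude) in the east–west direction) — adequate
at the basin-to-box scales involved and consistent with how the 3 × 3 km
site boxes and 15 km site spacing are defined.

Integration is fixed-step 4th-order Runge–Kutta, default timestep 30 min.
The integrator is exact to round-off in uniform flow and 4th-order
convergent on smooth fields; both properties are asserted in the test
suite (constant-flow displacement 0.1 m/s × 1 d = 8.64 km; solid-body
orbit closure within 0.1 % of the radius; error ratio ≈ 2⁴ under timestep
halving, measured between successive halvings so the dt-independent
discrete-field dynamics cancel). Trajectories are sampled on a fixed age
grid, default every hour: at ≤ 1 m/s a particle moves ≤ 3.6 km between
samples, comparable to the 3-km settlement box, so the risk of stepping
over a box unobserved is bounded; the cadence is an explicit
`integration_params()` knob. A particle that leaves the domain is
terminated; its later samples are missing, never outside the bounds. Land
cells contribute zero velocity to the interpolation, so particles stall
near coasts rather than acquiring spurious velocities or beaching
irreversibly — one defensible choice among several, flagged in the
documentation because observational studies rarely state theirs.

## The release model

Spawning is gated three ways, reflecting *Acropora*-style mass spawning:

* **Season** — May through August.
* **Moon** — only full moons whose local calendar date falls inside the
  season open a release window of ± 6 days around the moon, clipped to the
  season boundaries. An April moon whose window would poke into early May
  does not trigger spawning: the gating models lunar-cued spawning of a
  seasonal population, not a fixed date range. This convention, together
  with the next one, is what makes the release arithmetic come out exactly
  (798 events over 2019–2023).
* **Hour** — releases at 3-h intervals in the 18:00–24:00 evening window:
  18:00, 21:00 and 24:00 local time, with 24:00 kept on the same calendar
  day for windowing purposes. All schedule times are Japan Standard Time,
  because the spawning window is a local-time observation.

Each event releases a fixed particle count (default 200) placed uniformly
at random inside the source site's 3 × 3 km box. With the astronomical
calendar for 2019–2023 this yields 266 release days, 798 events, and
159,600 particles per site — the count the test suite and acceptance
script verify.

The astronomical calendar evaluates a standard truncated lunation-phase
series (polynomial mean phase plus ~40 periodic corrections in the solar
and lunar anomalies), converted from terrestrial time with a fixed
ΔT = 69 s — the actual 2019–2023 value to within fractions of a second,
and far below the one-day resolution at which the windows are defined. A
mean-synodic mode (29.530588 d from a configurable epoch) is provided for
fast, dependency-free tests.

## Dispersal percentages

For source A and sink B,

  P(A→B) = 100 · N(A→B) / N_all(A),

where a particle counts toward B if **any recorded position** with age in
(pre-competency, PLD] lies inside B's box. Key conventions, each tested:

* the age window is strict on the left (a 4.0-day-old passage does not
  count with the default 4-day pre-competency) and inclusive on the right;
* box membership is boundary-inclusive in local-km axes centred on the
  sink — immaterial at float precision, fixed for determinism;
* a particle counts once per sink regardless of repeat crossings (the
  statistic counts particles, not events), but may count toward many sinks:
  passing a site does not remove it (no settlement competition);
* the same rule applied to the source's own box gives the self-recruitment
  diagonal — including the pre-competency exclusion, which the source
  literature leaves unstated;
* detection uses recorded positions only, no segment–box intersection:
  conservative, matched to the sampling cadence, and equal by construction
  to the brute-force point-in-box oracle the tests compare against.

Island-group tables average P over all (source site, sink site) pairs of
the two groups, self-pairs included in diagonal cells, with the standard
deviation across pairs reported alongside. The strong-current region mask
marks cells whose temporal-mean **speed** (mean of |u|, not |mean u|; the
alternative is an option) over the spawning months exceeds a threshold,
default 0.4 m/s. The printed sources for this quantity disagree by a
factor of ten (0.4 m/s in the results text, 4 cm/s in a figure caption);
the package follows the results text and leaves the threshold
configurable. Pathway densities are Gaussian KDEs over all recorded
positions (MASS::kde2d with a Scott's-rule bandwidth per axis), explicitly
renormalized so the discrete integral over the evaluation grid is 1.

## The dispersal network

Sites are nodes; a directed edge A→B exists exactly where P(A→B) > 0 off
the diagonal, carrying the proportion p = P/100 and the distance
d = log(1/p). Distances are computed on **proportions, not percentages**:
percentages above 1 would give negative distances (and potential negative
cycles), and the stepping-stone product is only a probability on
proportions. Since p ≤ 1, every distance is nonnegative — asserted at
build time — so shortest paths are well defined.

**Betweenness centrality** (weighted by d, or unweighted hop counts) is
computed by igraph and normalized by 1/((n−1)(n−2)) over ordered pairs,
endpoints excluded; the tests verify it against a brute-force
all-simple-paths enumeration on 200 random graphs of up to 7 nodes.
Zero-distance edges (p = 1) are floored at 1e-12 for igraph's
positive-weight requirement; the floor is 10 orders below any realistic
distance difference.

**Stepping-stone dispersal** finds, for every ordered pair, the path
maximizing the product of per-generation proportions — equivalently
minimizing Σ log(1/p) — subject to a cap on the number of edges
("generations"). The solver is a generation-indexed dynamic program (a
hop-capped Floyd–Warshall): D_g(i,j) = min(D_{g−1}(i,j), min_k D_{g−1}(i,k)
+ d(k,j)), with per-level predecessor matrices for path reconstruction.
The uncapped result is the g = n−1 limit. Ties break toward fewer
generations, then toward the smallest intermediate node index, making
results deterministic; the tests require exact agreement (product, path
generations) with exhaustive simple-path enumeration. Because dispersal is
directional, the pairwise value compared with genetics is the **larger**
of the two directed proportions (`symmetrize_max()`); pairs unreachable in
both directions stay missing. "Generations to connect" a site set is the
largest over pairs of the smaller directed hop-count — pure reachability,
computed from unweighted shortest paths.

## Genetic comparison

Geographic distance is straight-line ("Euclidean") on a local
equirectangular plane centred on the compared sites' centroid, with a
haversine option for wider domains. Dispersal distance is log(1/p) of the
symmetrized stepping-stone proportion; pairs with p = 0 are a hard error
instructing the caller to restrict to connected pairs
(`largest_connected_subset()` does this greedily and deterministically).

The Mantel test correlates (Pearson) the vectorized upper off-diagonals
and builds its null by jointly permuting rows and columns of the second
matrix. Conventions, each a deliberate choice where the methodological
literature varies:

* default two-tailed on |R| (one-tailed options provided) — the tail used
  by a given study is rarely stated, and two-tailed is the conservative
  default;
* the identity permutation counts in numerator and denominator, so
  p ≥ 1/n_perm > 0;
* with excluded pairs (the outlier variant), the exclusion mask stays
  fixed to the original pair *positions* under permutation by default; a
  mask-follows-labels variant is available behind a flag, since either
  reading is defensible.

The permutation sampler is validated against exact enumeration of all 4!
relabelings of 4-site matrices (agreement within 0.02 at 10,000
permutations) and against vegan's one-tailed implementation for R and p.

## The synthetic test bed

The generators exist so that every stage is testable with known structure:

* **Jet fields** — a Gaussian-cross-section jet along a waypoint
  centerline (single width parameter, qualitatively a western-boundary
  current core), an opposing counter-current band offset to the jet's
  left, a periodic eddy perturbation, and seeded white noise. Fields are
  bit-identical per seed. Divergence-free flow is *not* claimed; only the
  pointwise construction is tested.
* **Island chains** — equal arc-length site spacing along a waypoint arc
  (default 15 km spacing scale), contiguous group labels.
* **F_ST** — F(i,j) = a + b·log(1/p(i,j)) + ε, mirrored, clipped below,
  zero diagonal: a direct encoding of the isolation-by-dispersal
  relationship the Mantel stage is supposed to detect. Defaults
  (a = 0.01, b = 0.005, sd = 0.003) put values in the 0.01–0.04 range
  typical of weakly differentiated broadcast spawners.

What passing tests show: the machinery is internally correct (oracle
equivalence), deterministic, and able to recover a known
dispersal–differentiation signal (at 7 sites, b = 0.005, sd = 0.003, the
association is detected at p < 0.05 in ≥ 90 % of 50 replicates) and a
known corridor geometry (a jet linking chain ends produces
P(end→far end) > P(end→mid) when mid-chain sites sit off the jet core).
What they do not show: anything about real oceans. The synthetic jet has
no assimilation, tides, shear instabilities, or shelf dynamics; real
current products and real F_ST matrices must be supplied for substantive
conclusions, and the headline percentages of any particular study depend
on operational-scale current fields and particle counts far beyond the
desk-scale runs used here.

## Problem sizes and runtime choices

The test suite and analysis drivers are sized for a single CPU: the
corridor check advects 20,000 particles (20 sites × 1,000) for 30 days at
a 30-min timestep in about a minute; the bundled study emulation in
`analysis/` uses one spawning year, a ±2-day lunar window and 20 particles
per event (24,000 particles total), with the full ±6-day window and
200-particle events left as configuration. Oracle comparisons use ≤7-node
graphs where exhaustive enumeration is exact. These sizes are stated here
as the package's own reproducibility envelope; all of them scale linearly
upward through `pipeline_config()`.

## Known limitations

* No settlement competition, age-dependent competence decay, or
  post-dispersal mortality: P is an upper bound on demographic exchange.
* Passage detection at the sampling cadence can miss fast transits of a
  3-km box when currents exceed ~1 m/s at the default hourly output;
  raising the cadence (or widening boxes in synthetic work) bounds this.
* The land-stall rule slows, but does not remove, particles entering
  coastal cells; beached larvae are not distinguishable from slowly
  drifting ones.
* The greedy connected-subset selection is maximal, not maximum; with
  heavily fragmented networks a larger comparable subset may exist.
* Mantel tests inherit their usual caveats (non-independence of pairs,
  sensitivity to a single outlier pair — hence the exclusion variant).
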