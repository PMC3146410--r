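---
title: "Standardizing travel-time inequality with complete spatial randomness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardizing travel-time inequality with complete spatial randomness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accessineq)
```

## The model

Geographic accessibility is operationalized as car travel time over the
road network from a demand block's centroid to its nearest facility.
Three ingredients:

**Travel time.** Every road segment carries a class-dependent legal speed
— 80 km/h (toll), 60 km/h (national or principal local road), 40 km/h
(other) — and a segment of length $\ell$ meters costs
$(\ell/1000)/v \times 60$ minutes. Routing minimizes network distance by
default (travel time optionally); the time reported for a block is the
time accumulated along its distance-minimizing route. All facilities are
candidates for every block, regardless of region membership: restricting
candidates to the block's own region would misstate access near
boundaries, and the Monte Carlo null below depends on the unrestricted
rule.

**Inequality.** For block times $x_i$ with population weights $w_i$,

$$D \;=\; \frac{\sum_i \sum_j w_i w_j \,|x_i - x_j| \,/\, W^2}{\bar x},
\qquad W = \sum_i w_i,\quad \bar x = \sum_i w_i x_i / W .$$

$D$ is the relative mean difference: mean absolute pairwise difference
over the mean. With the $W^2$ (not $W(W-1)$) denominator it is exactly
twice the Gini coefficient — the package computes the Gini independently
through the Lorenz trapezoid formula and the test suite holds the identity
to $10^{-12}$ — and it is scale invariant, replication invariant, and
bounded in $[0, 2)$. Product weights $w_i w_j$ make the block-level
computation identical to the per-person computation on the exploded
sample, which is what representing a census block by its centroid and
count means. The implementation sorts once and uses prefix sums
($O(n \log n)$); the $O(n^2)$ double sum serves as the oracle in tests,
never as the implementation.

**Standardization.** $D$ confounds the facility layout with the background
geography (where people live, how roads run). To isolate the layout
effect, the expectation $\bar D$ of $D$ is estimated under complete
spatial randomness: conditional on the observed count, facility locations
are i.i.d. uniform over the region. Per replicate, the facilities inside
the target region are relocated to a fresh uniform draw (outside
facilities stay fixed), every within-region block is reassigned to its
nearest facility among all of them, and $D$ is recomputed. After 99
replicates, $\bar D$ is the mean of the 99 simulated values *and* the
observed one (100 values), and the standardized ratio is
$R = D/\bar D$. Regions are ranked ascending by $R$; ties share the lower
rank.

Conditioning on the observed count is deliberate: the homogeneous Poisson
process underlying CSR factorizes into a Poisson count and, given the
count, uniform locations; relocating a fixed number of facilities
implements the conditional law, which is the comparison a planner wants
(same resources, random placement).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| speeds | 80 / 60 / 40 km/h | legal car speed by road class; overridable per class |
| `weight` | `"distance"` | what "nearest" minimizes; `"time"` optional |
| `n_reps` | 99 | CSR relocations per region; $\bar D$ then averages 100 values |
| `snap_tolerance` | 0.5 m | endpoint merge radius when building the network — absorbs digitization jitter without collapsing real intersections |
| `mode` | `"network"` | `"euclidean"` bypasses routing for fast exploration |
| `pop_meanlog`, `pop_sdlog` | 3, 1 | log-normal block populations in the generator (right-skewed, median ≈ 20) |

Because nearest-by-distance assignment is speed-free and $D$ is scale
invariant, multiplying every speed by a constant changes no $D$, no
simulated $D$, and no $R$ — bit for bit. The suite asserts this.

## Numerical and design choices

*Routing endpoints.* Blocks and facilities — including CSR-relocated
facilities — are snapped to the nearest network node (Euclidean, ties to
the lowest node index) and no approach distance is added. At block
granularity the approach leg is far below the segment resolution; the
choice is recorded in result metadata (`snap_relocated`). Whether the
original study snapped relocated facilities is not determinable from the
published account; this is the package's interpretation, stated as such.

*Tie-breaks.* Grids make equal-length routes generic, and their travel
times differ. Among weight-minimizing routes the implementation
deterministically returns the one best on the *other* metric, by adding an
epsilon of the secondary metric to the routing weight ($10^{-6}$
min-per-meter-scale, perturbations ≤ 1 mm / ≤ $10^{-3}$ min — far below
any meaningful gap). Facility ties at equal weight go to the lowest
facility id.

*Unreachable pairs.* A block that cannot reach any facility raises an
error naming the blocks rather than returning infinity — silent
infinities would corrupt $D$. Pairs unreachable only for *some*
facilities simply drop those candidates, which keeps CSR replicates on
multi-component networks well defined.

*Degenerate inputs.* All access times zero make $\bar x = 0$ and $D$
undefined: an explicit error, also per replicate (with the replicate
index) inside the Monte Carlo. Zero-population blocks ride through I/O
but never enter statistics. Geographic-looking coordinates (all within
±180/±90) are rejected at read time: the pipeline is strictly planar
meters.

*CSR sampling.* Rejection from the bounding box, with polygon membership
via even-odd ray casting (outer rings minus holes). A quadrat chi-square
on 10,000 points and an L-shaped support check guard uniformity.

*Per-region randomness.* Each region draws from a stream seeded by the
base seed plus a hash of the region id, so adding or removing a region
never perturbs another region's replicates.

*Weighted quantiles.* Box-plot summaries use type-7 interpolation on the
conceptually exploded per-person sample; with integer weights this equals
`quantile(rep(x, w), type = 7)` exactly. CSV output is written at 3
decimal places; JSON sidecars keep full precision.

## The synthetic generator

`make_scenario()` builds a square region, a grid road network spanning it
(principal-class roads through the middle row and column, the rest
"other"), log-normally populated blocks, and one of four facility
layouts: `regular` (centered lattice), `clustered` (blocks and facilities
around shared Gaussian centers), `circular` (blocks on a ring, facility
at the center — the optimal-location limit where all distances are equal
and $D = 0$ in Euclidean mode, up to cos/sin rounding), and `random`
(facilities themselves a CSR draw). Everything is reproducible from the
seed.

The generator emulates the *geometric structure* that drives the method —
skewed populations, clustering, mixed road classes — not any real
prefecture: road topology is a lattice, regions are squares, and
population placement ignores terrain. Passing tests therefore demonstrate
the correctness and calibration of the machinery (e.g. that `random`
layouts give mean $R \approx 1$ over replicate studies, checked over 50
studies of 99 replicates each), not that any particular real region's
published $D$ would be reproduced; that would require the original
block-level census geography, which is not public. The published
area-level table for Oita Prefecture ships with the package
(`oita_area_summary()`), and everything derivable from it — ratios,
aggregates, both rank orders and their reversal — is recomputed in the
acceptance checks. One wrinkle: its printed $D/\bar D$ for Hokubu yields
3.158 at three decimals while the published ratio column prints 3.159,
evidently computed before rounding; comparisons allow the half-unit
input-rounding bound ($2 \times 10^{-3}$).

Problem sizes in the shipped checks — up to 120 blocks, 6 facilities,
11 × 11 grids, 99 relocations, 50 replicate studies (Euclidean mode for
the replicated null) — were chosen so the whole suite exercises every
path in seconds while keeping Monte Carlo error well inside the asserted
bands.

## Limitations

Car-only travel at legal speeds (no congestion, turn restrictions,
one-way streets, or multi-modal transport); centroid aggregation of
blocks; relocation confined to the region boundary; no capacity
constraints or gravity/floating-catchment formulations; point estimates
only (no Monte Carlo p-values — the ratio, not a test, is the indicator).
Pooled multi-region rows report mean time and $D$ only: $\bar D$ is a
per-region construct.
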