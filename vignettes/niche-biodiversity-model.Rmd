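---
title: "A niche-environment null model of global biodiversity patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A niche-environment null model of global biodiversity patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichescape)
library(dplyr)
```

## The model

`nichescape` asks how much of the spatial arrangement of biodiversity is
fixed before any biology happens, by the geometry of climatic tolerance
alone. The model population is not a sample of real species but the
*complete combinatorial pool* of rectangular (presence/absence)
Hutchinsonian niches on one or two climatic axes: every amplitude from a
narrow steno-therm/-hygric interval up to the full domain width, at every
admissible position. A niche colonizes a grid cell in a given month iff
the cell's monthly climate value lies inside its closed tolerance
interval on every axis; no dispersal limitation, no biotic interactions,
no stochastic extinction. Any structure in the resulting richness maps is
therefore a mathematical consequence of the niche-environment
interaction — the relevant null model is a mid-domain effect in the
Euclidean space of climate, not in geographic space: mid-domain climate
values are contained by more of the admissible intervals than extreme
values, so places whose climate sits near the middle of the domain can
host more species.

Assumptions worth keeping in view:

- **Equilibrium occupancy.** Every niche fully occupies every suitable
  cell; richness is an upper envelope, not a prediction of abundance.
- **Monthly climatology is the only environment.** Temperature for the
  ocean (surface or seabed), temperature and precipitation jointly for
  land (both axes must be satisfied in the same month).
- **Niche uniqueness** (competitive exclusion): no two pool members share
  an identical interval set; with allopatric speciation enabled, the same
  niche can carry several species only in spatially disjoint ranges.

## Niche construction and exact arithmetic

On an axis with domain [ρ_min, ρ_max], minimum amplitude α₁, amplitude
increment µ and start step s, the pool has amplitudes α_i = α₁ + (i−1)µ,
i = 1..p with p = ⌊(α_max−α₁)/µ + 1⌋, α_max = ρ_max − ρ_min, and for each
amplitude q_i = ⌊(α_max+s−α_i)/s + 1⌋ starts from ρ_min in steps of s.
Ends y = x + α may overshoot ρ_max by up to s; those niches are retained
(the standard pool counts require them — dropping them changes r).

With µ = s = 0.1 these floors are numerically delicate: accumulating
0.1 in double precision and flooring produces counts that differ from
exact evaluation. All construction arithmetic therefore runs on integer
multiples of a base unit (0.1 °C, 1 mm), inferred per axis. Under exact
arithmetic the thermal construction (−1.8 to 44 °C) yields **101,474**
niches — an independent brute-force enumeration in the test suite agrees
— whereas accumulated floating point can lose a few dozen intervals.
Package counts are therefore internally exact and reproducible, and the
derived two-axis product pool has R = 101,474 × 930 = 94,370,820.

The default parameter sets are:

| axis | ρ_min | ρ_max | α₁ | µ | s | r |
|---|---|---|---|---|---|---|
| temperature (°C) | −1.8 | 44 | 1 | 0.1 | 0.1 | 101,474 |
| precipitation, fine (mm) | 0 | 3,000 | 100 | 100 | 50 | 930 |
| precipitation, coarse (mm) | 0 | 3,000 | 100 | 400 | 200 | 72 |

Two-axis pools are kept lazy (R ≈ 10⁸ is never materialized); monthly
richness for the *full* product pool factorizes over axes, and
`sample_pool()` draws members directly by global index for the sampled
runs, recording the sampling correction ϕ = 1/fraction.

### The mid-domain property, precisely

The containment count c ↦ #{niches ∋ c} peaks at the domain midpoint —
but strictly only when the midpoint lies on the start lattice
ρ_min + s·ℤ. Off-lattice values fall between the short intervals and the
count oscillates with period s; the interval family as a whole is
symmetric about (ρ_min + ρ_max + s)/2 because of the overshooting last
start. All parameter families above have lattice-aligned midpoints and
satisfy strict midpoint maximality (tested by scanning 100 constant
climates); for arbitrary specs the package's tests assert the underlying
symmetry instead. As s → 0 relative to the domain the distinction
vanishes (for the thermal pool it is 0.05 °C).

## Colonization and the presence policy

Presence is evaluated *per month*; annual richness D is the mean of the
12 monthly counts and Φ the count of species present in at least one
month. A strict all-months residency rule is available
(`policy = "all_months"`) but is not the default: under strict residency
the monthly stability index ψ10 = Σφ_m/(12Φ) is identically 1, which
contradicts the wide range of stability values the per-month rule
produces across zones (deep benthos near 1, strongly seasonal land and
nerito-pelagic cells far below); only the per-month reading makes the
stability index informative.

Monthly counts use order-statistics counting
(#{x ≤ v} − #{y < v} over sorted starts/ends), so mapping runs cost
O((cells + niches)·log) per month regardless of pool size. The union
field Φ genuinely requires per-niche presence and is evaluated in niche
chunks; for lazy product pools it is unavailable (Φ does not factorize
over axes) — the summary metrics that need it are computed from sampled,
materialized pools, which is also how the canonical speciation runs are
designed.

For the light-requiring neritic benthos, richness is down-weighted by a
beta-type response to annual seabed light, w(e) = v·((e_max−e)/(e_max−e_opt))·((e−e_min)/(e_opt−e_min))^((e_opt−e_min)/(e_max−e_opt))
with defaults v = 1, e_min = 0, e_opt = 20, e_max = 70 E m⁻² yr⁻¹: zero
in darkness and beyond tolerance, exactly v at the optimum.

## Allopatric speciation

On the coarse grid (2°; the fine mapping grid is refused for this stage)
each connected component of a niche's suitable range is one
pseudo-species. Conventions, each configurable:

- **Rook (4-neighbour) connectivity** by default: "separated by at least
  one cell" treats diagonal contact as separation; queen (8) available.
- **Longitude wrap on** by default: oceans are zonally continuous, so a
  range crossing the date line is one species. No adjacency across poles.
- **Suitability = per-month presence** (≥1 tolerated month), matching
  colonization; whether patches connected in some months only are one
  species is genuinely ambiguous, so the strict rule is exposed as the
  same policy switch rather than guessed.

Labeling runs on an `igraph` component decomposition of the adjacency
edge list; the test suite checks it against an independent flood-fill
oracle on hundreds of random masks including wrap cases. Species areas
sum great-circle cell areas (edge-midpoint spans, Earth radius
6,377.221 km — the same constant as every distance in the package; at 2°
resolution the cell-area error of this quadrilateral approximation is
well under a percent, and the sphere is tiled to within 2% even at 10°).

## Summary metrics and scaling

ψ1 is the *sampled* pool size (the pool actually simulated), ψ2 the
number of occupied niches, ψ4 the mean number of range components per
occupied niche, and the total pseudo-species is

ψ5 = ψ2 · ψ4 · ϕ.

A variant formula with ψ1 in place of ψ2 circulates, but published
summary tables are internally consistent only with ψ2 (e.g. the global
ocean surface row: 24,112 × 13.17 × 4 ≈ 1.27 × 10⁶); the ψ1 form is
treated as a misprint. ψ6–ψ8 are the median and quartiles of the
species range-area distribution (linear interpolation between order
statistics, the default quantile rule); ψ9 = 100·ψ6/zone area; ψ10
averages the cellwise stability unweighted over valid zone cells
(area-weighting is available but changes nothing qualitatively; the
aggregation rule is not pinned down externally, so the simplest one is
the default). Stability is kept as the fraction in (0,1]; some published
tables print it ×100.

Realm totals scale to reference eukaryote counts (catalogued
1,233,500 + 193,756 = 1,427,256; estimated 10,950,000) by
Θ = Θ_T + Θ_M, k = Θ/n_ref, scaled realm count = realm Θ/k — so the
scaled counts sum to the reference exactly by construction.

## Gradients and validation

LBG profiles take the per-latitude median across longitudes, requiring
at least 5 contributing cells (else the latitude is undefined). The
per-longitude LBG matrix standardizes richness once globally to [0,1]
(per-latitude standardization would erase the gradient itself) and
histograms it in 0.05 bins per latitude; the top bin is closed so the
global maximum lands in exactly one bin, and each row sums to 100%.
Constant maps are a degenerate-input error, not a silent zero.

Map validation reports per-cell Pearson r (each valid cell one
observation) with its nominal p, plus n*: the smallest n ≥ 3 at which
t = r·√((n−2)/(1−r²)) exceeds the two-sided 5% critical value with n−2
degrees of freedom. This deterministic inversion is this package's
definition — a gauge of how robust the correlation is to the effective
sample sizes that spatial autocorrelation leaves — and is not claimed to
reproduce any previously published n* values, whose exact adjustment
procedure is specified elsewhere and not restated here.

## The synthetic world

The generator emulates exactly the statistical structure the analysis
relies on, with one seeded noise field per variable:

- zonal annual-mean SST linear from 29 °C (equator) to −1.8 °C (poles);
  the equatorial default is set so the annual-mean profile crosses the
  thermal pool midpoint (21.1 °C) near 23° latitude, which is what makes
  the marine LBG peak in the 20–40° bands with an equatorial dip;
- seasonal cycles antiphased between hemispheres (northern July maximum),
  amplitude zero at the equator growing linearly to its polar value
  (8 °C SST, 18 °C land air temperature);
- monthly precipitation with an equatorial rain-belt peak (250 mm),
  subtropical dry-belt minima near ±25° (background 25 mm) and a
  midlatitude wet band (80 mm), mildly seasonal on land;
- a meridional supercontinent (30% of longitudes) so the terrestrial
  gradient is defined at every latitude;
- bathymetry monotone from the coast: shelf reaching 200 m over 3 cells,
  slope to a 4,500 m abyss, populating all three benthic bands;
- cold, nearly aseasonal seabed (temperature relaxing to 2 °C, seasonal
  amplitude decaying with depth) and seabed light decaying exponentially,
  clipped to [0, 33.43] E m⁻² yr⁻¹ and exactly zero below the 200 m
  photic cutoff.

The noise is deliberately *constant across the 12 monthly layers*
(drawn once per variable): monthly-independent noise would manufacture
spurious seasonality, break the bitwise-identical-months contract when
seasonal amplitudes are zero, and push ψ10 below 1 on an aseasonal
world for purely artificial reasons.

What the generator does **not** emulate: realistic coastlines and
continental configuration, zonally asymmetric climate (monsoons, western
boundary currents), interannual variability, and any covariance between
temperature and precipitation beyond their shared zonal structure.
Passing tests on this world show that the pipeline recovers the
gradient contrasts *implied by the assumed climatic structure*; they are
not evidence about real climatologies, which users can supply through
the CSV grid interface at their own resolution.

```{r gradients, fig.width = 5, fig.height = 4}
world <- generate_world()
zones <- make_zone_masks(world$bathymetry)
marine_pool <- sample_pool(build_axis_niches(thermal_axis_spec()),
                           0.25, seed = 1)
surf <- richness_field(marine_pool, world$sst, zone = zones$surface_all,
                       compute_union = FALSE)
autoplot(lbg_median(surf))
```

```{r land-gradient, fig.width = 5, fig.height = 4}
land_pool <- build_product_pool(thermal_axis_spec(),
                                precipitation_axis_spec())
land <- richness_field(land_pool,
                       list(temperature = world$land_temp,
                            precipitation = world$precip),
                       zone = zones$land)
autoplot(lbg_median(land))
```

## Numerical choices and degenerate inputs

- Closed intervals on both ends; a value exactly at an interval end is
  contained. Boundary inclusion is applied consistently everywhere
  (containment, counting, suitability).
- Depth-band ties go to the shallower band ("0–200 m" read as an
  inclusive upper bound): a 200 m cell is neritic, a 2,000 m cell is
  shelf-edge.
- Longitudes live in [−180, 180), grids are cell-centre registered, and
  a cell invalid in any source grid (or any month) is excluded from
  every simulation using that grid — no imputation anywhere.
- Bilinear regridding invalidates any target cell whose stencil touches
  an invalid source cell; refining the default world from 2° to 0.25°
  and recomputing richness reproduces the coarse pattern with r > 0.95.
- Empty species sets summarize with ψ2 = 0, undefined quartiles and a
  warning; all-land grids give empty marine masks with a warning; a
  constant richness map is a degenerate input for the LBG matrix.

## Problem sizes and limitations

The package is pure R. Mapping runs are cheap at any pool size thanks to
the counting fast path (the full 9.4 × 10⁷-niche terrestrial product
pool maps a 2° world in seconds). Stages that need per-niche work — the
union field Φ and speciation — scale linearly in niches × cells; the
bundled examples and tests therefore use sampled pools of a few hundred
to a few thousand niches on the 2° world, which leaves every metric
well-defined while keeping runs interactive. Full-scale runs (25,349
thermal niches against a global 2° ocean) are supported but take tens of
minutes; `chunk_size` bounds their memory.

Beyond scale, the main limitations are the model's own idealizations:
equilibrium full-range occupancy (inflating ψ4 where real dispersal is
limited), no palaeoclimatic barriers (allopatric counts reflect today's
climate only), rectangular niches (no response shape within the
interval), and the synthetic world's zonal symmetry noted above.
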