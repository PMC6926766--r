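---
title: "Methods: landscape eco-security assessment, hotspot analysis and ecological zoning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landscape eco-security assessment, hotspot analysis and ecological zoning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landsec)
```

## The problem

Resource cities — cities whose economy grew around the extraction of oil,
coal or minerals — accumulate characteristic ecological damage in their
urban fringe: vegetation is destroyed around extraction sites, degraded
land salinizes, and grassland coverage declines outward from the damaged
core. `landsec` implements a complete, reproducible pipeline for assessing
the *landscape ecological security* of such a fringe from categorical
land-use rasters and city-level statistics, locating statistically
significant insecurity clusters, and partitioning space into risk-warning
and protection zones.

The pipeline has four analytical stages:

1. a **DPSIR composite index** per 1 km x 1 km assessment unit and year;
2. **spatial autocorrelation**: global Moran's I and local Getis-Ord Gi*
   hotspot fields with a seven-grade classification;
3. **time-space overlay zoning** of two yearly hotspot fields plus a
   scale-optimized, FDR-corrected hotspot field into eight named zones;
4. **minimum-cumulative-resistance (MCR) cost distance** from the
   ecological sources, delineating the protection area.

A seeded synthetic-landscape generator supplies study scenarios with the
structure the analysis assumes, so every stage is testable end to end
without any external data.

## The composite index

Indicators are organised in the DPSIR causal frame — Driving forces,
Pressure, State, Impact, Response — with dimension weights
$w_D = 0.05$, $w_P = 0.2$, $w_S = 0.2$, $w_I = 0.5$, $w_R = 0.05$ and
within-dimension weights as configured in `indicator_config()`. The index
of unit $k$ in year $t$ is the two-level weighted sum

$$\mathrm{LES}_{kt} \;=\; \sum_{d} w_d \sum_{i \in d} w_i\, y_{ikt},$$

where every raw indicator $x$ is linearly normalized to $y \in [0,1]$ over
the pooled set of all units and all years jointly,
$y = (x - \min)/(\max - \min)$, reversed for indicators whose polarity is
negative (risk, non-ecological proportion, degradation intensity). Pooling
the normalization across years is what makes the index comparable through
time; normalizing each year separately would erase exactly the trend the
assessment is meant to show.

The eleven indicators:

* **D1** urbanization growth intensity (city urbanization change over
  national change between consecutive assessment years), **D2** per-capita
  GDP;
* **P1** the resource-curse coefficient — the city's share of national
  resource production divided by its share of national secondary-industry
  output, **P2** an environmental performance index averaging
  $(x_i/g_d)/(X_i/G)$ over configured pollutant/consumption categories;
* **S1/S2** grassland degradation and restoration intensities
  $K = \Delta S / S / \Delta t$ from the land-use transfer matrix of the
  step ending at the assessment year, **S3** the proportion of
  non-ecological land (farmland, construction, saline-alkali);
* **I1** the ecological risk index
  $\mathrm{ERI}_k = \sum_i (A_{ki}/A_k) E_i F_i$ (interference x
  vulnerability), **I2** ecological resilience
  $\mathrm{ECO}_{res} = \sum_i A_i P_i / C_i$ with elasticity $P_i$ and
  fragmentation $C_i = N_i/A_i$ (patch density), **I3** the ecosystem
  service value $\mathrm{ESV} = \sum_i A_i\,\mathrm{VC}_i$;
* **R1** ecological-construction investment intensity (investment over
  GDP).

D, P and R derive from citywide statistics and are constant across units
within a year; S and I vary per unit. Change indicators (D1, S1, S2) are
undefined for the first assessed year; missing indicators have their
weights renormalized within their dimension rather than being imputed as
zero, which would bias the index downward exactly where data are thinnest.

**Coefficient tables.** The four per-class coefficient tables ($E_i$,
$F_i$, $P_i$, $\mathrm{VC}_i$) shipped in `indicator_config()` are
*synthetic stand-ins*, ordered by ecological intuition: construction and
saline-alkali land carry high interference and vulnerability and low
elasticity; water and woodland carry the highest service values. Every
value is plain configuration and should be replaced with locally
calibrated coefficients for real studies.

**AHP.** `ahp_weights()` derives weight vectors from pairwise comparison
matrices as the normalized principal eigenvector, with Saaty's consistency
ratio $\mathrm{CR} = ((\lambda_{max}-n)/(n-1))/\mathrm{RI}(n)$ flagged
above 0.1. The shipped default weights are taken as configuration; the AHP
machinery is provided so users can derive their own from expert
judgements.

**Open polarity questions.** The printed polarity of P1 and P2 is positive
(more pressure, higher security), which may look counter-intuitive; the
defaults keep the published orientation and `indicator_config()` lets
users flip any polarity. Similarly S3 is implemented as the proportion of
*non-ecological* land per the land-use legend's ecological split, which is
the orientation consistent with its negative polarity.

## Spatial autocorrelation

Global Moran's I is computed in its classical form

$$I = \frac{\sum_i \sum_j W_{ij}(x_i-\bar x)(x_j-\bar x)}
           {S^2 \sum_i \sum_j W_{ij}},
  \qquad S^2 = \tfrac1n \sum_i (x_i-\bar x)^2,$$

with binary contiguity weights by default (queen adjacency of the unit
blocks; rook, row-standardized and fixed-distance-band weights are
available). Inference is reported twice: the analytic z-score under the
randomization assumption (with the usual $S_1, S_2, b_2$ moments), and a
permutation pseudo p-value
$(\#\{|I_{perm}| \ge |I_{obs}|\}+1)/(B+1)$ with a recorded seed, 999
permutations by default. The published weights scheme behind comparable
analyses is typically not stated; queen/binary is this package's
documented default, not a claim about any particular study.

Local clustering uses the Getis-Ord Gi* statistic with self-inclusive
neighbourhoods,

$$z_i = \frac{\sum_j w_{ij}x_j - \bar X \sum_j w_{ij}}
             {S\sqrt{\big(n\sum_j w_{ij}^2 - (\sum_j w_{ij})^2\big)/(n-1)}},$$

graded into seven classes: |z| >= 2.58 high, >= 1.96 middle, >= 1.65 low
(boundaries inclusive upward), sign separating hot from cold, else not
significant. A Jenks natural-breaks grading (`method = "breaks"`, exact
Fisher dynamic programming) is available for rendering; the confidence
method is the default because it is deterministic and has a sampling
interpretation.

The **optimized hotspot** variant emulates scale-selected hotspot
analysis: the global Moran z-score is profiled over candidate distance
bands (multiples of the unit spacing), the band at the first local peak is
selected, Gi* is computed at that band, and Benjamini-Hochberg FDR at the
configured level gates the grading. It is fully deterministic.

**Multiplicity.** The pipeline grades the yearly Gi* fields through the
same Benjamini-Hochberg gate (level 0.05) by default
(`hotspot_correction = "fdr"` in `pipeline_config()`). With ~400 units
tested simultaneously, an ungated field is guaranteed ~2.5% spurious
|z| >= 1.96 grades in *any* landscape, which would propagate into spurious
"restoration" zones for a perfectly stable landscape. Users who want the
classical ungated rendering can set `hotspot_correction = "none"`.

## Overlay zoning and the MCR protection area

The last two assessment years' hotspot fields and the final year's
optimized field are overlaid per unit through an explicit 63-row rule
table (`default_overlay_rules()`): persistent hot units become *core
protection* (promoted to *bottom-line protection* when the unit's dominant
class is water); hot in the final year only, *ideal protection*; not
significant in both years but optimized-hot, *ecological potential*; cold
in the final year only, *risk supervisory*; persistent cold graded by the
final-year intensity into *risk prevention*, *key restoration* and *core
restoration*; everything else *other*. The exact published partitioning
rules behind comparable studies are not printed anywhere; this table is
therefore shipped as an overridable configuration artifact and the test
suite asserts this documented table.

The *risk warning area* is the union of the five cold-derived zones; the
*protection area* unions the sources, ideal protection, buffer and
conflict zones.

The resistance surface combines two ranked maps with equal weight: land
use (water 1 ... construction 8) and overlay zone (core protection 1 ...
core restoration 8), giving per-cell resistances in [1, 8]. Cost distance
is exact Dijkstra over the 8-connected cell graph with step cost equal to
the mean of the two cells' resistances times the step length (cell size,
x sqrt(2) diagonally); the MCR model's outer monotone function is taken as
the identity since only the ordering and thresholds matter. Cells whose
accumulated cost from the core sources (core + bottom-line protection) is
below 30,000 resistance-metres, or below 14,000 from the potential sources
(ecological potential zones), join the protection area together with the
sources and the ideal-protection zones; within it, farmland and
construction cells are *ecological conflict* and the remainder is
*ecological buffer*. The thresholds are configuration with these
conventional defaults; they are in resistance x metres, so users working
at other cell sizes should rescale deliberately.

## The synthetic scenarios

`scenario_preset()` ships three named study conditions on a 20 x 20 km
domain (200 x 200 cells of 100 m — the 1-km assessment unit must be an
integer number of cells, so a Landsat-like 30 m cell is deliberately not
used) over the years 1980, 1990, 2000, 2010, 2017:

* **stable** — no oilfield strip, zero change rates; smoothing range 3
  cells, i.e. patches smaller than an assessment unit. This is a
  deliberately structure-poor negative control: unit-level values are
  close to exchangeable noise, so a correct pipeline should find *no*
  persistent cold clusters and no restoration demand.
* **degrade-only** — a 2-km-wide north-south strip of low-coverage
  grassland (an oilfield analogue: land already disturbed by extraction)
  degrades stepwise into saline-alkali land with per-step probability 0.3
  via the chain high -> medium -> low coverage -> saline-alkali
  (saline-alkali is absorbing, so its area is monotone non-decreasing).
  The surrounding landscape uses smoothing range 5 cells, giving multi-km
  patches and unit-level global Moran's I near 0.5 — the magnitude
  reported for real urban-fringe landscapes at this unit size.
* **degrade-then-restore** — as degrade-only, plus farmland outside the
  strip converting to high-coverage grassland at rate 0.15 per step once
  the year-2000 policy is active.

Class placement thresholds a seeded Gaussian-smoothed noise field by the
configured class proportions, ordered water, woodland, high/medium/low
grassland, saline-alkali, farmland, construction, so threshold neighbours
are ecologically plausible neighbours. The generator emulates the
*structure* the analysis assumes — contiguous patches, a contiguous
low-security strip, monotone degradation, a rise-then-decline oil curve —
and nothing else: there is no sensor noise, no classification error, no
sub-cell mixing, and the socio-economic series is a smooth parametric
economy. Passing tests on these scenarios therefore demonstrate that the
*methods* recover planted structure under controlled conditions, not that
any particular real landscape behaves this way.

Two cautions established during design, verified by experiment and worth
knowing before interpreting results:

* the strip-recovery Jaccard depends on the landscape realization: some
  seeds contain genuine insecure clusters far from the strip, which
  honestly enter the warning zones and dilute the overlap with the
  planted mask;
* with a *wide* strip (a large fraction of the domain), the global mean is
  dragged down far enough that the whole far field becomes one large
  significant high-value cluster at coarse scales — a real property of
  Gi*, not an artifact. The preset keeps the strip at 10% of the domain
  width partly for this reason.

## Numerical choices and degenerate inputs

* Normalization with a degenerate pooled range (max = min) maps to 0.5
  with a warning rather than failing, so a constant indicator carries no
  information instead of poisoning the index.
* Moran's I and Gi* raise an explicit undefined-statistic error on
  constant fields ($S^2 = 0$), matching their division-by-variance failure
  mode.
* Grade thresholds are inclusive upward (z = 1.96 is hot-middle).
* Edge assessment units truncated by the raster boundary are kept with
  their true smaller area; per-unit ratios remain well defined and no
  boundary landscape is discarded.
* Azimuth sectors are measured clockwise from grid north, centred on the
  eight compass directions; a unit centroid coincident with the study
  centre is assigned N by convention.
* Patch counting defaults to 8-connectivity (the landscape-ecology
  convention); the fragmentation definition is pluggable because the
  classical sources leave it underdetermined.
* All stochastic stages (scenario generation, permutation tests) consume
  explicit integer seeds and are bit-reproducible; the run manifest
  written by `run_pipeline()` records every seed and parameter needed to
  reproduce a run.

## Problem sizes

The shipped presets (400 assessment units, 40,000 cells, 5 years) run the
full pipeline in a few seconds; the test suite uses smaller domains
(16-144 units) for the exhaustive oracles — brute-force double sums for
Moran's I, literal Gi* formula evaluation, exhaustive path enumeration and
fixed-point relaxation for the cost fields — which are exact but scale
steeply. These sizes are the package's chosen study conditions; all
formulas are resolution-independent except the MCR thresholds noted above.

## Limitations

* No reprojection: all rasters are assumed co-registered; the I/O format
  is ESRI ASCII grid (GeoTIFF is out of scope for this package's I/O).
* The fragmentation index is patch density, not a full FRAGSTATS suite.
* The overlay rule table and coefficient tables are documented defaults,
  not estimates; results on real data are only as good as those inputs.
* The optimized hotspot variant emulates the published *idea* of
  scale-selected, multiplicity-adjusted hotspot analysis; it does not
  reproduce any proprietary tool's undocumented heuristics (incident
  aggregation, locational outlier trimming).

## A minimal run

```{r example, eval = FALSE}
library(landsec)
res <- run_pipeline(pipeline_config("degrade-only", seed = 1))
moran_summary(res)
res$report$warning$warning_km2
res$report$protection$protection_km2
table(res$hotspots[["2017"]]$grade)
```
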