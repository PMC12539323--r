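---
title: "Methods: drought impacts on gridded ecosystem services"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drought impacts on gridded ecosystem services}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters that matter, what
the synthetic landscape generator does and does not emulate, the numerical
choices, and the design decisions taken where the method left them open.
It states no empirical result that the test suite does not itself compute.

## 1. The analysis chain and its assumptions

The package targets a common study design in landscape ecology: a multi-year
stack of co-registered annual rasters on a common metric grid (nominally
1 km, 2000–2022), from which four ecosystem services are computed per cell
and year and then related to meteorological drought measured by the
standardized precipitation–evapotranspiration index (SPEI; unitless, more
negative = more severe drought).

**Water retention (WR, mm).** An InVEST-style retention adjustment of the
water-yield raster:

\[
\mathrm{WR} = \min(1, 249/\mathit{Velocity}) \cdot
\min(1, 0.9\,\mathit{TI}/3) \cdot \min(1, K_s/300) \cdot \mathit{Yield}.
\]

Each attenuation term is clamped to [0, 1], so retention never exceeds
yield; retention is non-decreasing in yield, conductivity and topographic
index and non-increasing in the velocity coefficient. Water yield itself is
an *input* (the InVEST water-yield model is not re-implemented), as are the
velocity coefficient, topographic index and saturated conductivity
($K_s$, cm/d). The source expression is typeset without division signs; the
form above is the standard, dimensionally consistent reading.

**Soil conservation (SC, t·hm⁻²·a⁻¹).** RUSLE with the adjustment factor as
printed in the source method:

\[
Q_{sc} = R \cdot K \cdot L \cdot S \cdot (1 - P \cdot C),
\]

with cover ($C$) and practice ($P$) factors in [0, 1]. Note this is *not*
the textbook $(1-C)(1-P)$ composition; both are available through
`rusle_variant = c("printed", "textbook")`, with "printed" the default for
fidelity. The six factor rasters are inputs; their own sub-models (R from
rainfall records, K from texture, LS from flow routing) are out of scope.

**Carbon sequestration (CS, t·km⁻²).** $G_V = 1.63 \cdot A \cdot \mathrm{NPP}$,
reported per area as $1.63\,\mathrm{NPP}$ since 1 g·m⁻² ≡ 1 t·km⁻². The
1.63 coefficient is applied literally; whether NPP is carbon mass or dry
matter is not asserted by the method and not resolved here.

**Food supply (FS, t·km⁻²).** Municipal grain totals $P_{sum}$ are
disaggregated over the zone's cropland cells proportionally to NDVI:
$P_i = \mathrm{NDVI}_i/\mathrm{NDVI}_{sum}\cdot P_{sum}$, then divided by
cell area to give a density. The estimator's defining property is exact
mass conservation per zone-year, which the tests verify to a relative
1e-9 over random layouts. Cropland cells with negative NDVI are excluded
from $\mathrm{NDVI}_{sum}$ (with a warning) rather than clipped to zero:
clipping would silently keep the cell in the denominator, exclusion keeps
all allocations non-negative and conservation exact. A zone with positive
grain total but no positive cropland NDVI is an error naming the zone,
because the allocation is then undefined.

**Drought classification.** SPEI is cut into five ordered classes on
half-open intervals, lower-open/upper-closed so each boundary value belongs
to the *more severe* class (SPEI = −1.0 is a medium drought): none
(> −0.5), slight (−1.0, −0.5], medium (−1.5, −1.0], serious (−2.0, −1.5],
extreme (≤ −2.0). The source method's own cutoff table sits in an
unavailable supplement; this is the standard SPEI grading consistent with
its four drought names, and it is fully configurable
(`drought_class_table()`). Drought frequency `SPEI_F` is the fraction of
years a cell spends in any drought class. For drought-degree
stratifications of cells (trade-off matrices, service distributions), a
cell's degree is the most severe class it attained over the record
(`cell_drought_degree()`); for drought vs non-drought comparisons, a
cell-year is a drought observation when its class is not "none". Both
pooling conventions exist because the method does not state which its
figures use; `stratify_es_by_drought()` exposes both modes. Mean
comparisons use Welch's unequal-variance t-test — the source reports star
levels without naming a test, and Welch is the conservative default.

**Trends.** Per-cell Theil–Sen slope (median of all pairwise slopes, in
units of the variable per calendar year; missing years are dropped pairwise
with calendar spacing kept) and the Mann–Kendall test with the tie-corrected
variance \( \mathrm{Var}(S) = [n(n-1)(2n+5) - \sum_t t(t-1)(2t+5)]/18 \) and
continuity correction \( z = (S \mp 1)/\sqrt{\mathrm{Var}(S)} \), $z = 0$
when $S = 0$. Two-sided p-values from the normal approximation;
significance maps coded −1/0/+1 at α = 0.05 by default. No prewhitening for
serial correlation is applied (a known limitation, below). A consequence of
the continuity correction worth knowing: $|S| = 1$ maps to $z = 0$, so sign
agreement between $z$ and $S$ holds only for $|S| > 1$.

**Constraint lines.** The upper boundary of the service-vs-SPEI scatter is
estimated by quantile segmentation: the SPEI range is split into 100
equal-width intervals, and within each interval holding at least
`min_count = 10` points the 99.9th percentile of the service is a boundary
point, placed at the bin midpoint. Percentiles interpolate linearly between
order statistics (R's `type = 7`); sparse bins are dropped rather than
merged (merging would move the bin's nominal location); at least 10
qualifying bins are required. Midpoints rather than within-bin mean x keep
the boundary abscissae independent of the x distribution. Three candidate
families are least-squares fitted to the boundary points: a quadratic hump,
a Gaussian hump with offset, and a cubic (the "convex-wave" morphology).
Goodness of fit ($R^2$) is computed on the boundary points, not the raw
scatter. Family *selection* cannot use raw $R^2$: the cubic nests the
quadratic and the Gaussian can mimic it, so the larger family would always
win. The winner is therefore the family with the smallest BIC,
$n\log(\mathrm{SSE}/n) + k\log n$ — which is exactly "maximum $R^2$" among
families of equal size, and under a true quadratic boundary lets the extra
cubic/Gaussian parameter win only when its likelihood-ratio gain exceeds
$\log n$ (about 4–5% of noise realizations, matching the package's
model-selection test). Families that fit exactly ($\mathrm{SSE} \le
10^{-12}\,\mathrm{SST}$) are resolved by parsimony: fewest parameters wins.
The drought-response *threshold* is the SPEI value where the fitted
boundary attains its maximum: the root of $dy/dx$ with $d^2y/dx^2 < 0$,
solved analytically for the polynomial families and by bracketed
root-finding (tolerance 1e-10) for the Gaussian. If no interior maximum
exists on the observed range, the maximizing endpoint is reported with the
flag `boundary_max`, and all derivative roots found in range are returned
(`critical_points`) so a reader can audit the "inflection point" choice —
the method's own wording is ambiguous between maxima and other critical
points; the maximum is implemented.

**Bundles.** Cell profiles (period-mean WR, SC, CS, FS plus SPEI_F;
per-year stacking available via `period_stat`) are z-scored — a
zero-variance feature is a named error, since its z-score is undefined —
and clustered with an online self-organizing map: rectangular 2×2 map (one
unit per bundle, since the analysis expects exactly four bundles; any
`grid_shape` can be requested), Gaussian neighbourhood, learning rate
decayed linearly 0.5 → 0.01 and radius from half the map diagonal → 0.3
over 500 epochs, codebook initialized from seeded sample rows,
presentation order reshuffled per epoch from the same seed. Training runs
in compiled code (src/som.cpp) and is bit-reproducible given the seed.
Cells map to their best-matching unit; empty units reduce the realized
bundle count with a warning. Bundle naming/semantics are left to the
analyst; `summarize_bundles()` reports the per-bundle feature signature
(median, IQR, mean, SD) to support it.

**Trade-offs and synergies.** Pearson correlations among period-mean
services (and SPEI_F) across the cells of each stratum; negative =
trade-off, positive = synergy. P-values use the exact t-transform of r with
n−2 df; stars follow the reporting convention (* < 0.05, ** < 0.01,
*** < 0.001); no multiple-testing correction is applied, matching the raw
stars the method reports. Observations are cells (period means) by default,
cell-years optionally — the observation unit is not stated in the method.
Spatial autocorrelation is deliberately ignored in the significance, as in
the source; the p-values are therefore optimistic for spatially smooth
fields (limitation, below).

**Attribution.** Each service is regressed on twelve drivers (TEM, PRE, ET,
SPEI_F, EL, SL, NDVI, WUE = GPP/ET, SOC, RSMC, GDP, POP) by a *surrogate
predictor*, and per-cell attributions are exact Shapley values computed by
full enumeration of all $2^{|N|}$ feature subsets with the combinatorial
weights $|S|!(|N|-|S|-1)!/|N|!$ (enumeration is bounded at 15 features;
12 features = 4,096 subsets). The value function is interventional:
$f_x(S)$ is the mean prediction over a background set with the features in
$S$ pinned to the instance — the mainstream choice for tabular models; a
conditional expectation would require a density model the method does not
define. Efficiency ($\sum\phi = f(x) - E[f]$), symmetry, dummy and
linearity are verified as tests, including agreement with an independent
permutation-averaged oracle for $|N| \le 5$. The surrogate is pluggable by
contract (any named-column prediction function); the default is ordinary
least squares, with a GAM option (mgcv) for nonlinear responses. A
random-forest surrogate — the choice in the source method — is not
available in this environment; since the attribution contract is
model-agnostic and the forest internals are not the contribution, the
default linear surrogate stands in. One consequence: importance *ratios*
on pure-noise targets behave differently than under a forest (no positive
noise floor), so the null test checks that spurious importances are small
on the signal scale rather than flat in ratio.

## 2. The synthetic landscape: what it emulates, and what a green test means

`generate_landscape()` produces the full input stack from one seeded
configuration. Its defaults state the emulated world once:

- **Grid and calendar**: 60×60 cells of 1 km (any size), 23 years labelled
  2000–2022, 2% of cells invalid everywhere (one shared mask).
- **Drought**: annual SPEI is a year effect (N(0.1, 0.35)) plus a per-cell
  drought-proneness offset; the years 2011 and 2022 are forced drought
  years, in which cells take stratum-specific targets (−0.35, −0.9, −1.4,
  −1.9, −2.4 for none…extreme proneness) chosen to sit safely inside the
  default severity classes, so planted stratum labels coincide with
  realized classifications and the grid-mean drought-year SPEI falls below
  −1 — mirroring the observed behaviour of the study region's record
  (annual means near 0 with drops to about −1 in its two drought years).
- **Boundaries**: each (service, land-use) pair carries a quadratic hump
  boundary $g(x) = h\,\max(1 - \kappa(x - x^*)^2, 0.05)$ over SPEI, with
  apexes defaulting to the published pattern (forest WR 0.81, forest SC
  0.96, most apexes above −0.5) and heights in natural units. A cell-year's
  service is $g(\mathrm{SPEI})\cdot V$ with $V \in [0,1]$, so services
  *never* exceed the boundary, and with probability `envelope_fraction`
  (5%) $V$ is drawn from Beta(20, 1), densely populating the upper
  envelope so that 99.9th-percentile extraction has something to find.
- **Bundles**: each cell belongs to one of four bundles (mixing fractions
  0.30/0.15/0.30/0.25) whose centroids are service *levels* (fractions of
  the local boundary height) — a conservation bundle, a fragile bundle, an
  agricultural bundle, a carbon bundle. Land use and drought proneness are
  drawn conditional on bundle, so bundle structure appears in SPEI_F and in
  the land-use composition as well. True labels are recorded in
  `$truth` for recovery tests.
- **Trade-offs**: requested within-stratum correlations between service
  pairs (default: WR–FS r = −0.25 among extreme-proneness cells) are
  planted through a Gaussian copula on the cell levels. Because the bundle
  centroids already induce cross-service covariance, the generator solves
  the mixture algebra for the latent correlation $\rho^*$ that yields the
  requested *observable* Pearson r:
  \(\rho^* = (\rho_t\sqrt{V_pV_q} - \mathrm{Cov}_b)/\sigma^2\),
  where $\mathrm{Cov}_b$ and $V_{p,q}$ are the bundle-mixture moments of
  the centroid levels under the distribution conditional on the stratum
  (and on cropland for pairs involving FS, where food supply is defined),
  and $\sigma$ is the within-bundle level SD (0.12). An infeasible request
  ($|\rho^*| > 0.99$) is clamped with a warning. Temporal noise (level
  jitter SD 0.03, envelope replacement 5%) attenuates the realized
  correlation by under 5% by design — these SDs were chosen small for
  exactly that reason.
- **Drivers**: back-solved so the service equations reproduce the planted
  targets exactly — Yield = WR-target / attenuation, R = SC-target /
  (K·L·S·(1−PC)), NPP = CS-target / 1.63 — and flavoured so the
  attribution stage has real structure to find: PRE tracks the WR level,
  SOC the SC level, WUE the CS level, elevation is bundle-dependent
  (highest in the fragile bundle). Drought cell-years (SPEI ≤ −0.5) take
  temperatures in 23–25 °C and precipitation in 400–600 mm, planting the
  hot-dry pocket that the binned SPEI surface should isolate. Cropland
  NDVI within each zone-year is proportional to the FS target, which makes
  NDVI-share allocation reproduce the targets exactly and is why the
  planted NDVI *trend* applies to non-cropland cells only.
- **Zones**: contiguous rectangular blocks; zone grain totals are the sums
  of the planted per-cell targets, so allocation closes exactly.

What the generator does **not** emulate: real geography and spatial
autocorrelation (cells are exchangeable given their bundle/stratum; no
smoothing is applied, and the method's own rasters' autocorrelation is
unknown), monthly dynamics, cross-year persistence of drought, measurement
error correlated across variables, and map projections (the grid is a
local metric grid). A green test therefore establishes that the
*estimators recover what was planted under the stated noise*, not that the
package reproduces any particular region's published values — those derive
from undeposited rasters and are echoed here only as planted parameters
(apex 0.81/0.96, r = −0.25, drought years 2011/2022).

## 3. Numerical choices and degenerate inputs

- Validity is NA-based: one mask shared by all rasters; a cell invalid in
  land use is invalid everywhere (enforced at generation and at read).
- Percentiles: linear interpolation (`type = 7`) everywhere, matching the
  documented boundary-point definition; an independent sort-based
  implementation backs the tests.
- Division guards: WUE marks ET = 0 cells invalid; velocity ≤ 0 is a
  domain error (the attenuation term is undefined); a zone with positive
  grain but zero cropland NDVI is an allocation error.
- All-tied trend series: $S = 0$, $z = 0$, $p = 1$ — a result, not an
  error. Fewer than 3 (slope) or 4 (test) finite values is an error.
- Shapley weights use log-factorials; efficiency holds to ~1e-15 in the
  axioms tests, well inside the 1e-8 contract.
- Seeds: every stochastic stage derives its seed deterministically from
  the master seed and a stage tag (kept below 2^31); reruns of the same
  configuration are bit-identical, which the pipeline manifest (MD5 per
  output file, config hash) makes checkable.
- Fixture I/O writes doubles with 17 significant digits, so a write/read
  round trip is bit-exact; files are verified against manifest checksums
  on read, and shape/cell-size mismatches are alignment errors naming the
  offending rasters.
- Rasters travel as single-band ESRI ASCII grids and configs as JSON: the
  environment provides no GeoTIFF or YAML support in R, and both
  substitutes are plain text with the same information content.

## 4. Design decisions taken where the method was open

- **Candidate family catalog** fixed to {quadratic hump, Gaussian hump,
  cubic}: the two reported morphologies ("hump-shaped", "convex-waved")
  plus the natural smooth alternative; configurable per call.
- **BIC for family selection** (§1): raw maximum-$R^2$ cannot prefer a
  nested-smaller family, so it would contradict the expected behaviour on
  quadratic boundaries; BIC reduces to maximum $R^2$ among equal-size
  families and is reported alongside each family's $R^2$.
- **Threshold = boundary maximum**, with all derivative roots reported,
  because "inflection point" in the source is ambiguous.
- **SOM hyperparameters** (2×2 map, Gaussian neighbourhood, 0.5 → 0.01,
  500 epochs): the source gives none; these are conventional and the map
  shape/epochs are configurable. One unit per bundle avoids a second
  clustering step on a large map.
- **Interventional value function** with a seeded 100-row background and
  500 attribution instances per bundle by default at the module level
  (pipeline defaults are smaller — 20 instances, 50 background — to keep a
  full 100×100 run interactive); instances and background are seeded
  subsamples.
- **Static vs dynamic storage**: physically time-invariant factors
  (terrain, soil erodibility, conservation practice, velocity,
  conductivity) are stored once rather than per year; annual variables are
  year-indexed arrays. This is a storage choice, not a modelling one.
- **Stratification conventions** (dominant class per cell; drought onset
  at SPEI ≤ −0.5) follow the class table's own drought onset.

## 5. Known limitations

- Significance of trends and correlations ignores spatial and serial
  autocorrelation; on smooth fields the stars are optimistic. Prewhitening
  and spatially corrected inference are out of scope.
- The constraint boundary is estimated from pooled cell-years, so its
  abscissa distribution is whatever the landscape provides; bins far from
  the bulk of SPEI values may be sparse, and apex recovery in strata whose
  SPEI never approaches the apex relies on the fitted family's shape
  rather than local data.
- The 99.9th percentile needs on the order of 200+ points per bin before
  it separates from the bin maximum; with fewer points the boundary is
  effectively the within-bin maximum and correspondingly noisier.
- Exact Shapley enumeration is deliberately bounded (≤ 15 features);
  sampling approximations are out of scope.
- The linear default surrogate understates interaction-driven importance;
  use the GAM surrogate (or plug in any predictor honouring the contract)
  when interactions matter.
- Annual resolution: no within-year drought timing, no crop-calendar
  effects on food supply.
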