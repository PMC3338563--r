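---
title: "Valuing and mapping crop pollination benefits: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valuing and mapping crop pollination benefits: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollvalue)
```

## The valuation model

`pollvalue` prices the pollination-attributable share of crop
production. For crop $i$, country $j$ and year $t$, the benefit is

$$V(t) = \sum_i \sum_j pp_{ij}(t)\, pq_{ij}(t)\, dr_i\, inf_j(t)\, ppp_j(t),$$

the product of the nominal producer price ($US\$/t$), the production
quantity ($t$), the crop's pollination dependency ratio ($dr_i \in
[0,1]$, with lower/median/upper literature bounds), the inflation
correction factor to the reference year (1 in the reference year), and
the purchasing-power-parity factor (1 for the reference country).
Conceptually the model first attributes a share $dr_i$ of the harvest to
animal pollination and then values that share at corrected producer
prices. This is a production-cost (replacement-value) perspective: it
does not net out substitution between production factors, so it bounds
an attributable-net-income valuation from above.

Two companion series decompose change over time. The
pollination-weighted quantity $Q(t) = \sum\sum pq\,dr$ is the physical
twin of $V$ in dependency-weighted tons, and the price signal
$P(t) = V(t)/Q(t)$ is the implicit average corrected price of
pollination-dependent output. By construction $V = P\,Q$ holds exactly
wherever $Q > 0$; the package treats this identity as a structural
invariant and the test suite enforces it to $10^{-9}$ relative. A
staple baseline applies the same machinery to pollination-independent
staples with $dr \equiv 1$, giving the comparison series for quantities,
production value and prices.

### Weighted quantities and monetary corrections

Whether the quantity series should carry the inflation and
purchasing-power corrections is genuinely ambiguous: corrected tons are
dimensionally odd, and applying the correction to both $V$ and $Q$
cancels it in $P = V/Q$. The package defaults to uncorrected tons —
keeping the price signal in $US\$/t$ — and exposes
`weighted_quantity(..., monetary_corrections = TRUE)` for the corrected
variant, so both readings are available and the choice is explicit in
code.

### Gaps and scenario bounds

Real national statistics have reporting gaps: country-years with
production but no price, or no correction factors. `align_panels()`
counts and flags such rows and excludes them from all sums — exclusion
is conservative and reported (`alignment_coverage()`), rather than
silently imputed. An optional `impute = "country-mean"` switch replaces
a missing price with the country-year mean over reporting crops, for
sensitivity analysis only.

Valuation uncertainty inherited from the dependency literature is
propagated by evaluating $V$ under the lower, median and upper $dr$
columns (`scenario_bounds()`); monotonicity of $V$ in $dr$ guarantees
`lower <= median <= upper` at every point, which the tests check on
random panels.

## Vulnerability indicators and trends

Two ratios measure how exposed an economy is to pollinator decline:
benefit over GDP, and benefit over agricultural GDP
($GDP \times$ agricultural share). Values above 1 are arithmetically
possible when crop statistics and macroeconomic statistics disagree;
they are flagged `"inconsistent"` rather than truncated, because they
are a data-quality signal worth surfacing. The global aggregate is a
ratio of sums, $\sum_j V_j / \sum_j GDP_j s_j$ — not a mean of national
ratios — so that it reads as "the part of the (agricultural) world
economy attributable to pollination" and is dominated by large
economies exactly as the underlying quantity is.

Country trends are ordinary least-squares slopes of value on calendar
year (`linear_trend()`, `country_trends()`); countries observed for
part of the window get slopes over their available years with
`n_years` reported. Trend correlations across countries (e.g. benefit
trends against beehive-count trends) use Pearson's $r$ on the country
intersection. Outlier handling is deliberately manual: exclusions are
explicit id lists, never automatic detection, so every removal is
visible in the call. Relative changes between two anchor years are
$v(t_1)/v(t_0) - 1$; a zero or missing base value flags the country as
undefined (excluded from comparison plots) instead of producing an
infinite change.

## The gridded benefit map

On a 5-arc-minute latitude–longitude lattice, per-cell benefit for one
crop is

$$v(x,y) = \mathrm{yield}(x,y)\ \times\ \mathrm{area\ fraction}(x,y)\ \times\ pp_{j(x,y)}\ \times\ dr,$$

in corrected $US\$$ per hectare of *total* cell area. Multiplying the
harvested-hectare yield by the cultivated fraction moves every crop to
the same whole-cell reference area, which is what makes the per-crop
maps summable. Prices and purchasing-power factors are national (looked
up through a country-zone raster — lattice-exact, no polygon overlay),
because sub-national prices are generally unavailable.

Mask semantics are three-valued and deliberate:

* yield and area fraction both present → valid benefit value;
* yield present, area fraction absent → `missing_data`: the benefit is
  unknowable there, and maps should show it as such;
* yield absent → plain nodata.

In the all-crop total, a cell is nodata only if *no* crop is valid
there; known contributions are kept even where other crops are
`missing_data`, so the total is a conservative lower estimate. Cells
whose area fractions sum above 1 across crops (an artefact of
allocating administrative statistics to grids) are counted and reported
but not renormalised — there is no defensible renormalisation without
the upstream allocation model.

Zonal totals convert $US\$/ha$ to absolute dollars with the spherical
band area of each cell (authalic radius 6371.0088 km), giving the
consistency bridge to the national valuation: on rasters whose layers
re-aggregate to national production, zonal totals equal national $V$
to floating-point accuracy (the acceptance suite requires $10^{-6}$
relative on a 20-country, 5000-cell world).

Rasters are matrix-backed (`pv_raster`), cell-centre registered,
north-up, geographic CRS, with plain-text ESRI ASCII grid I/O — a
deliberately small spatial core that keeps every operation (areas,
masks, zonal sums) inspectable and exactly testable.

## Trend-surface regression

`fit_trend_surface()` describes the mapped pattern with a penalized
additive model of $\log$ benefit: a bivariate tensor smooth of
temperature and precipitation (the smooth analogue of "temperature ×
precipitation interaction"), a univariate smooth of cropland fraction,
and optionally a two-dimensional coordinate smooth that absorbs spatial
structure the predictors miss. Zero and missing cells are removed
before the natural-log transform (`build_regression_table()` reports
the exclusion counts); the log base only rescales coefficients and does
not affect explained variance. Smoothness is selected by generalized
cross-validation; the reported statistic is the proportion of deviance
explained (for the Gaussian fits used here, equivalent to an $R^2$).
Basis dimensions default small — tensor margins of 4–5, $k = 20$ for
cropland, $k = 50$ for coordinates — and are configurable; a seeded
`subsample` argument caps the fit size on large rasters. The model is
descriptive: it is explicitly not intended for projecting climate
effects on pollination benefits.

Calibration is checked on constructions with known answers: a
pure-noise response must yield essentially zero explained variance, an
exact linear function of cropland a near-perfect fit, and a smooth
function of temperature and precipitation plus noise at a known
signal-to-noise ratio must be recovered within ±0.1 of the construction
$R^2$ at $n = 2000$.

## What the synthetic generator does and does not emulate

`generate_world()` produces panels with the statistical features the
pipeline is sensitive to: very unequal country sizes (log-normal,
$\sigma = 1$ log-unit), per-crop production levels with mild
country-specific growth and 5% multiplicative noise, producer prices
with AR(1)-like multiplicative log noise ($\sigma = 0.15$,
autocorrelation 0.6), per-country inflation rates of 1–6%/yr
compounding toward the final reference year, and constant per-country
purchasing-power factors in $[0.8, 3]$ with the first country as
reference. Nominal prices are stationary, so corrected prices drift
downward at roughly the inflation rate — the generator makes no attempt
to reproduce real-world price trends, only the noise structure around
them.

Two optional construction-known truths make recovery testable end to
end: `target_ag_dependency` builds GDP from the realized benefit so the
agricultural dependency indicator equals the target *exactly* in every
country-year, and `beehive_trend_correlation` draws beehive trend
slopes correlated with benefit trend slopes at a requested $\rho$
(beehive series are exactly linear, so estimated slopes equal the
constructed ones and the estimated $r$ sits in the ordinary sampling
band of $\rho$).

`generate_rasters()` places countries as contiguous latitude blocks
around the equator — sufficient for zonal logic and trivially
verifiable, with no pretence of realistic country shapes — and
allocates each national tonnage across the country's cells with random
cultivated fractions (per-cell sums kept below 1) and a uniform
national yield chosen so zonal re-aggregation is exact by construction.
Temperature falls with absolute latitude, precipitation is a smooth
field, and cropland tracks the total cultivated fraction with noise.
The map year defaults to 2000, the year for which sub-national crop
allocations exist in the real data landscape.

Passing tests on these worlds therefore demonstrates the *mechanics* —
sums, joins, identities, masks, zonal consistency, estimator
calibration — not agreement with real FAO magnitudes, spatial
clustering of agriculture, reporting biases, or country-specific data
quality, none of which the generator models.

All draws derive from a single base seed through fixed per-component
offsets, so adding a new generated component never shifts the draws of
existing ones, and equal seeds give byte-identical outputs (including
written grid files).

## Numerical choices and problem sizes

Sums are computed with R's extended-precision accumulation; permuting
input rows changes grouped sums by far less than the $10^{-9}$ relative
contract the tests enforce. Products are summed directly — prices are
never pre-averaged — to avoid weighting bias. Degenerate inputs are
flagged, not dropped: zero weighted quantity flags the price signal
undefined, zero GDP flags the indicator undefined, zero base-year
values make indexing an error.

The shipped tests and the acceptance script use deliberately modest
problem sizes — panels up to 150 countries × 10 crops × 17 years,
rasters up to 5000 cells, regressions at $n = 2000$ — chosen so the
full suite runs in seconds while every property under test (exactness,
ordering, recovery bands) is already binding at that scale.

## Known limitations

* No currency conversion: all monetary inputs are assumed pre-converted
  to US$ (the 1993–2009 restriction of FAO price data guarantees this
  for the intended sources).
* No trade adjustment: benefits are attributed to producing countries;
  importers' dependence on foreign pollination is out of scope.
* No welfare-economics valuation (consumer surplus, attributable net
  income): the production-cost approach is used throughout.
* The coordinate smooth mitigates, but does not formally correct for,
  spatial autocorrelation.
* The synthetic generator is a testing instrument, not a calibrated
  emulator of real agricultural statistics.
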