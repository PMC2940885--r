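---
title: "Environmental-envelope habitat similarity: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Environmental-envelope habitat similarity: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habsim)
```

## The method

habsim implements a grid-based environmental-envelope method for predicting
the potential distribution of a species from the conditions of its native
range. The workflow has five stages:

1. **Envelope extraction.** Field plots in the native range are overlaid on a
   stack of aligned environmental raster layers (by convention 1 km cells);
   each plot receives the value of the cell containing it, with no
   interpolation. Per variable the envelope records n, min, max, mean,
   standard deviation, standard error and the mean absolute deviation about
   the mean (MAD), plus the set of soil taxonomy codes observed at plots.
2. **Normalization.** Environmental factors live on incommensurable scales
   (metres, millimetres, degree-days), so each continuous layer is
   standardized by the envelope: $z = (x - \bar y)/\mathrm{MAD}_y$. The MAD
   is the classic robust scale used before Manhattan/Minkowski distances in
   clustering; an envelope mean maps to exactly 0 and one MAD of deviation
   to 1.
3. **Distance and similarity.** Each cell's normalized vector is compared to
   the envelope centre (the zero vector) by the weighted Minkowski distance
   $d(q) = (\sum_i w_i\,|z_i|^q)^{1/q}$, with $q = 1$ the Manhattan and
   $q = 2$ (the default) the Euclidean distance. Distance is converted to a
   0–100 % *similarity rate* (below), and the categorical soil layer is
   scored by *grade division*: the deepest taxonomy level (order < suborder
   < group < subgroup < family) the cell's soil shares with any envelope
   soil, divided by 5.
4. **Classification and zoning.** Cells with similarity ≥ 95 % are
   *favorable*, 90–95 % *suitable*, below 90 % *slightly appropriate* (both
   class bounds inclusive at the bottom of the class: 95.0 is favorable,
   90.0 is suitable). The cell classification is aggregated to counties by a
   coverage rule and tallied by class and province.
5. **Validation.** The predicted county set is compared with a survey-record
   county set by three-way decomposition: congruent (intersection),
   prediction-only (potential habitat), and survey-only (prediction misses).

## Interpretation choices that are ours

Two steps of the published method family are underdetermined, and habsim
makes its choices explicit and configurable rather than asserting them as
anyone else's.

**Distance → similarity.** There is no canonical mapping from an unbounded
distance to a bounded similarity rate. habsim uses
$s_c = 100\cdot\max(0, 1 - d/d_\mathrm{ref})$, which sends the envelope
centre to 100 % and the reference distance to 0 %. The default
`d_ref_policy = "max"` takes $d_\mathrm{ref}$ as the largest finite distance
over the analysis extent: it is scale-stable (rescaling all layers leaves
the map unchanged) and parameter-free, but it makes the similarity scale
relative to the extent analysed — analysing a larger, more extreme landscape
stretches the scale. `"percentile:P"` (robust to a few extreme cells) and
`"fixed:v"` (an absolute scale in normalized units, comparable across
extents) are one flag away. Thresholds of 95/90 % should therefore be read
against the chosen policy, not as absolute environmental bands.

**Combining climate and soil.** The soil score is categorical and the
climate score continuous; the published method family does not state the
combination. The default `soil_mode = "weighted"` blends
$(1-w)\,s_c + w\,s_s$ with $w = 1/(k+1)$ for $k$ continuous variables, i.e.
soil counts as one factor among $k+1$. `"mask"` instead zeroes any cell
whose soil shares nothing with the envelope at the order level, and `"off"`
ignores soil.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `q` | 2 | Minkowski exponent; 1 = Manhattan. $d$ is non-increasing in `q`. |
| `favorable_min`, `suitable_min` | 95, 90 | class thresholds in % |
| `soil_mode`, `soil_weight` | weighted, $1/(k+1)$ | soil combination rule |
| `d_ref_policy` | `"max"` | distance-to-similarity reference |
| `tau` | 0.05 | a county "has" a class when ≥ 5 % of its covered cells attain it |
| `variable_weights` | all 1 | per-variable weights inside the distance |

The coverage rule `tau` deliberately yields *per-class membership flags*
rather than a partition: a county can sit in both the favorable and the
suitable list, so zoning tallies use inclusion–exclusion
($|A\cup B| = |A| + |B| - |A\cap B|$), which the test suite asserts exactly.
Region areas are cell counts × cell area (the raster convention, exactly
testable), not polygon geometry. Because cell classes are mutually
exclusive, the combined favorable+suitable area has no double counting even
when county lists overlap.

In the validation report, survey-coverage and survey-only percentages use
the survey size as denominator and prediction-only uses the prediction size
— the only bases under which the three parts are each interpretable as "a
share of the set they describe". Rendered percentages round half-up to one
decimal at print time only; raw values are kept. Note that with 101 surveyed
and 98 congruent counties the survey-only share is 2.97 %, which renders as
3.0 under half-up rounding (a truncating renderer would print 2.9).

## Statistical companions

`coefficient_of_variation()` is $C_v = \sigma/|\mu| \times 100\,\%$; the
absolute mean keeps it positive for below-zero temperature means, and
`sd_from_se()` bridges "mean ± SE" tables to $\sigma$. The shipped
*Rheum tanguticum* reference table satisfies the identity
$C_v = (\mathrm{SE}\sqrt{n})/|\mu| \times 100$ on every row to one rendered
decimal, which the tests assert. `one_way_anova()` is the classical
between/within mean-square F; the grouping unit is whatever
`habitat_group` label the plot table carries (county or town — the package
does not privilege either). `pca_contributions()` eigen-decomposes the
correlation matrix by default (covariance optional); because eigenvector
sign is arbitrary, each component is oriented so its largest-magnitude
loading is positive, making loadings deterministic and testable.

## The synthetic landscape generator

All tests run against generated fixtures with known ground truth. The
generator (`landscape_spec()`, `make_landscape()`) emulates:

* **Continuous layers** (default 11, named and centred like an
  alpine-plateau species' envelope): linear gradients in evenly rotated
  directions $\theta_l = 2\pi(l-1)/k$ plus i.i.d. Gaussian noise. The
  half-amplitude is 3× the variable's native half-range — the landscape
  spans a region several times wider than the native envelope, as a
  national extent does — and the noise sd is 0.5 % of the amplitude,
  reflecting smooth interpolated national surfaces whose local roughness is
  small against continental gradients.
* **A planted truth zone**: cells within `truth_frac` × amplitude of the
  centre on *every* layer. With evenly rotated gradients this is a regular
  $2k$-gon (nearly a disc) around the landscape centre; its area has a
  closed form that the tests check at `noise_frac = 0`.
* **Soil**: a Voronoi mosaic over random sites, coded by a generated
  5-level taxonomy (a national-scale 12/29/61/235/909 hierarchy scaled down
  to 4/8/16/28/40), giving contiguous patches with realistic hierarchical
  structure.
* **Counties and provinces**: a rectangular tiling (default 10×10 counties
  in 2×2 provinces) emitted as GeoJSON polygons.
* **Plots and surveys**: plots are drawn uniformly without replacement from
  truth-zone cells (default 206); surveys derive from the true county set
  with configurable omission/commission.

One master seed fans out to fixed per-stage substreams, so every stage is
independently reproducible.

**Why `truth_frac = 0.105`.** Under the defaults the distance is, up to
noise, proportional to the distance from the landscape centre, and the
largest distance occurs at the corners ($r_\mathrm{max}$, the half
diagonal). The 90 % similarity contour therefore sits near
$0.1\,r_\mathrm{max}$, shifted slightly outward (to ≈ $0.109\,r_\mathrm{max}$)
where the default soil term contributes its full weight. Planting the truth
zone with radius $0.105\,r_\mathrm{max}$ places its boundary at that
decision contour, which makes planted-truth recovery a *sharp* test: the
classifier must reproduce the zone's boundary, not merely find an
over- or under-sized blob. The recovery suite requires cell-level Jaccard
≥ 0.8 on each of 10 seeds, and the full pipeline (plots → envelope →
similarity → classification → county zoning → survey overlap) must cover
≥ 95 % of the survey at zero omission/commission.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: topographic heterogeneity (real mountain climates
vary at sub-kilometre scales; our noise is white and small), correlated and
nonlinear gradients (real temperature variables are strongly collinear;
ours point in spread directions), irregular county geometry, spatially
structured survey error, and biotic interactions. Recovery results on these
fixtures demonstrate algorithmic correctness, not predictive skill on real
landscapes.

Default problem sizes — a 200 × 200 grid of 1 km cells with 11 layers, 100
counties and 206 plots, with 50 × 50 landscapes for oracle comparisons —
keep every envelope, distance and zoning computation exactly checkable
while remaining comfortably within a laptop-scale run.

## Numerical and degenerate-input choices

* **Point-in-cell ties**: cell `[r, c]` covers a half-open square; a point
  on an interior shared edge belongs to the east/south neighbour, and the
  extent's maximum edges are closed. Deterministic, so plot sampling is
  order-invariant.
* **Region membership**: a cell belongs to the polygon containing its
  centre (even-odd rule); cells whose centre lies in no polygon are
  unassigned and excluded from fractions.
* **Zero-MAD variables** carry no distance information under MAD
  normalization and would divide by zero; they are excluded with a warning
  (strict mode errors). A landscape where *every* cell ties the envelope
  centre has no positive reference distance and is an error rather than a
  map of all-100s.
* **Missing data**: envelopes exclude missing values variable-wise; any
  nodata among used layers makes the cell nodata in the similarity map —
  conservative, never imputed.
* **Out-of-extent plots** are an error by default; a permissive mode drops
  them with a logged count, because silently dropped plots corrupt
  envelopes.
* **Alignment**: stacking misaligned layers is an error naming the
  offending layer; the package never resamples or reprojects.

## Known limitations

The envelope is a box-plus-centroid summary: multimodal or strongly
correlated native niches are blurred (no kernel densities, no Mahalanobis
option). The similarity scale under the default `"max"` policy is relative
to the analysed extent. Soil grading treats all taxonomy levels as equally
informative steps. Raster I/O is ESRI ASCII grid and polygon I/O is GeoJSON;
projections are out of scope — all inputs must share one planar
kilometre-scale frame.
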