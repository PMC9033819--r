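---
title: "Methods: eco-environmental quality evaluation for mining areas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eco-environmental quality evaluation for mining areas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

maeeq evaluates the eco-environmental quality (EEQ) of coal-mining regions
from a stack of co-registered indicator rasters and attributes its spatial
structure to drivers. This vignette is the package's account of the model,
its assumptions, the tunable parameters, the numerical choices, and what
the synthetic test bed does and does not demonstrate.

## The evaluation model

The analysis consumes 13 indicators spanning geomorphology (elevation,
slope, aspect, geomorphic type), climate (annual average precipitation and
evaporation), hydrology (aquifer specific yield, river-system distance),
land and vegetation (land-use type, NDVI), and human activity (mining
intensity, population density, surface subsidence). All layers must share
shape, cell size and origin; `align_stack()` refuses mismatches rather than
resampling, because silent resampling corrupts the evaluation. Any cell
missing in one indicator is excluded everywhere (the joint mask): the
sample matrix handed to the statistics has complete rows by construction.

### Standardization

Quantitative indicators are min-max standardized over the scene's valid
cells, with a per-indicator polarity: positive polarity maps larger raw
values to better quality (`(x - min) / (max - min)`), negative polarity
reverses the ramp. Polarities are configuration, not behaviour baked into
the code; the shipped defaults treat precipitation, aquifer specific yield
and NDVI as positive, evaporation and population density as negative, and
default the terrain variables to positive. In an arid mining belt,
elevation correlates with precipitation and vegetation while lowlands
concentrate settlement and disturbance, which motivates those defaults —
but any deployment should revisit them per `indicator_spec()`.

Qualitative indicators are mapped to expert grades 1 (worse) to 5 (better)
by a five-equal-division grade map and the observed grades are then
range-normalized like any other quantity. Two of the shipped maps deserve
comment. The land-use map places bare surfaces — desert and unused land —
together at grade 2, between construction land (1) and cultivated land (3),
since both are ecologically comparable bare ground. The binary maps
(geomorphic type, mining intensity, surface subsidence) use the extreme
grades {1, 5}, so after range normalization they standardize to {0, 1}.
When a qualitative layer shows a single observed grade there is no range to
normalize; the value is anchored on the 1–5 scale as `(g - 1) / 4` rather
than erroring, so degenerate scenes (e.g. nothing mined) stay analyzable.

### Weights by genetic-algorithm projection pursuit

Indicator weights come from projection pursuit: find the unit direction
$c$ ($\sum_j c_j^2 = 1$) whose one-dimensional projection
$V_i = \sum_j c_j\,x_{ij}$ of the standardized sample best combines global
spread with local clustering,

$$Q(c) = S(c)\, D(c), \qquad
S(c) = \operatorname{sd}(V), \qquad
D(c) = \sum_{i}\sum_{j} (R - r_{ij})\,\mathbf{1}\{r_{ij} < R\},$$

with $r_{ij} = |V_i - V_j|$. $S$ uses the $n-1$ denominator. $D$ is the
literal double sum over all ordered pairs including $i = j$ (each diagonal
term contributes $R$), with a strict step function ($f(0) = 0$); the
brute-force oracle in the tests shares exactly this convention so the
equivalence checks are well-posed. The window radius $R$ defaults to
$0.1\,S(c)$, recomputed per candidate direction — the prevailing convention
in the projection-pursuit literature — and can be overridden with a
constant. The optimal direction's squared components are the weights,
$u_j = c_j^2$, which sum to one by the constraint and are invariant to the
direction's sign.

One behaviour of this index deserves a caveat. On a min-max standardized
stack, a balanced binary indicator (a qualitative layer standardizing to
{0, 1}) simultaneously maximizes projection spread — a 50/50 split has
standard deviation 0.5, more than any smooth unit-interval field — and
produces perfectly tight projection clusters, which the density term
rewards heavily. Projection pursuit therefore tends to concentrate weight
on balanced binary layers when they are present, as the worked example in
the README shows on the synthetic scene's two-band landform layer. This is
a property of the objective, not a defect of the optimizer (the dense
angular sweep agrees); deployments that consider it undesirable can pass a
constant window radius `R`, supply externally fitted weights to
`run_pipeline()`, or stratify binary indicators out of the weighting step.

The maximization uses a real-coded genetic algorithm: tournament selection
(size 2), arithmetic crossover, Gaussian mutation (sd 0.1), projection of
every individual back onto the unit sphere, and elitism, which makes the
best-objective trace non-decreasing. The default configuration is
population 400, crossover probability 0.8, mutation probability 0.3, 200
elites; stopping is `max_generations` (200) or 30 stalled generations with
relative improvement below 1e-8, whichever comes first — "until Q stops
increasing" needs an operational tolerance. The optimizer is bit-reproducible
under its seed. Because $D$ is superlinear in $n$, samples above 5,000 rows
are searched on a seeded random subsample (default 2,000; disclosed via a
message) and the reported final objective is recomputed on the full sample.
The tests and the acceptance script run the GA at population 24–60 and
12–60 generations: at those problem sizes (m = 2–13, planted structure)
the GA already matches a dense angular sweep to within 0.1%, and the trace
plateaus long before the cap.

### Index, grading, and area accounting

The quality index is the cellwise weighted sum of the standardized layers,
in [0, 1] by construction. It is graded into five ordinal classes (1 worse
… 5 better) with Jenks natural breaks computed by Fisher's exact dynamic
program — deterministic, and oracle-testable against exhaustive partition
search, unlike the heuristic re-seeding variants. Ties prefer the smaller
upper class. Intervals are lower-closed/upper-open except the top class
(closed above); a value sitting exactly on a shared boundary joins the
upper class. Inputs beyond 3,000 values are first thinned to 3,000 equally
spaced order statistics of the sorted sample — deterministic, and accurate
to well below a class width — which keeps the quadratic program tractable
on full raster surfaces. Grading can also apply externally supplied
thresholds, e.g. to reuse breaks fitted on another scene or published for a
reference area. Per-region area reports count valid cells times the cell
area (`cell_size`² m²); proportions are of the region's valid area and sum
to 100 by construction.

### Spatial autocorrelation and LISA

For spatial analysis the index is aggregated to square analysis units
(default 500 m, the conventional scale for mining-area EEQ lattices): unit
value is the mean of valid fine cells, and units below 50% valid coverage
are dropped to stabilize border means. Contiguity weights are queen by
default (rook available), row-standardized.

Global Moran's I uses the standard normalization
$I = \frac{n}{S_0}\,\frac{\sum_i\sum_j w_{ij} d_i d_j}{\sum_i d_i^2}$.
Textbook presentations sometimes carry the weight matrix into the
denominator and an extra factor of $n$; that variant is not bounded by
[-1, 1] and does not match values produced by the standard interactive
spatial-analysis tools, so the package implements the standard statistic
and reports the literal variant alongside (`I_literal`) for transparency.
Inference is by random permutation (default 999, seeded), one-sided in the
direction of the observed statistic; the null expectation is $-1/(n-1)$.

Local Moran's I, $I_i = n\, d_i \sum_j w_{ij} d_j / \sum_k d_k^2$, is
tested by conditional permutation — unit $i$ held fixed, its neighbours'
values drawn from the remaining units — and a unit is labelled with its
Moran-scatter quadrant (H-H, L-L, H-L, L-H) only when its pseudo p-value
passes `alpha` (default 0.05, i.e. the 95% confidence convention). Zero
deviations are assigned to the "high" side of the quadrant split; they
carry $I_i = 0$ and never reach significance, so the choice is cosmetic.

### Geographic detector

Drivers are analyzed on the same unit lattice. Continuous drivers are
discretized with Jenks breaks — by convention nine strata for continuous
indicators, six for land use, two for the binary indicators — and
categorical drivers keep their categories. Factor detection reports
$q = 1 - \mathrm{SSW}/\mathrm{SST}$ with population variances inside the
within-stratum term (so $N_h \sigma_h^2$ telescopes to the literal
within-group sum of squares). Significance uses a seeded 999-permutation
pseudo p rather than the noncentral-F approximation: the permutation test
is assumption-free and directly testable.

Interaction detection computes q on the cross-stratification (distinct
label pairs) and classifies against the single-factor q values in this
order: below both (nonlinear attenuation), between them (single-linear
attenuation), above their sum (nonlinear enhancement), equal to the sum
within 1e-9 (mutual independence — exact equality of reals never fires),
otherwise bilinear enhancement. The printed criteria in common references
overlap ("greater than max" also covers "greater than sum"); the ordering
resolves the overlap in favour of the more specific branch, as the
geodetector literature does. Risk detection runs two-sided Welch t-tests
between all stratum pairs with at least two samples, with
Welch–Satterthwaite degrees of freedom, and returns the stratum-mean
profile from which linear versus wavelike responses are read.

### Zoning

Significant L-L clusters become the management zone (intensive ecological
rehabilitation), significant H-H the close-attention zone (good quality at
risk from future mining), and significant spatial outliers (H-L, L-H) the
protective zone. Non-significant units get an explicit "none" label so
area accounting covers every retained unit. Zoning is a pure function of
the LISA table.

## The synthetic test bed

Real deployments of this model start from satellite imagery, DEMs and
survey data that cannot ship with a package, so `make_scene()` generates a
13-layer scene with planted ground truth. Quantitative layers are white
noise smoothed by a moving-average filter (radius `autocorr_range`, default
5 cells) and rescaled to [0, 1]; cross-indicator correlation is induced by
loading several layers on a shared latent elevation field — precipitation
and NDVI positively, evaporation and population negatively — mirroring the
elevation–precipitation–vegetation coupling of arid mining belts.
Mining intensity is a contiguous mined block covering `mined_fraction`
(default 20%) of the domain; subsidence is a set of discs inside that
block; land use is a quantized smooth mosaic; landform a two-band
elevation split. A latent quality field is built as the weighted sum of
the standardized layers under known weights — mining intensity carries the
largest latent weight (0.28), so the mined block visibly depresses quality
— plus Gaussian noise (sd 0.02). The default domain is 100 × 200 cells at
100 m, i.e. a 10 × 20 km scene that yields an 800-unit lattice at 500 m:
large enough for stable Moran/LISA and geodetector behaviour, small enough
that the full pipeline runs in minutes on one CPU.

What the scene does *not* emulate: radiometric noise, classification error
in land-use maps, interpolation artefacts in climate surfaces, nonstationary
anisotropic autocorrelation, and missing-data patterns of real mosaics
(the default scene has a full joint mask). Passing tests therefore
demonstrate that the statistics and their couplings are implemented
correctly and recover planted structure — not that the shipped polarity or
grading defaults are right for any particular coalfield.

`make_stratified_response()` complements the scene for geodetector
calibration: Gaussian draws around per-stratum means with the analytic
expectation $q = \sigma^2_{\text{between}} / (\sigma^2_{\text{between}} +
\sigma^2_{\text{within}})$ stored for assertion; a two-stratum design with
a 2σ mean gap has q = 0.5 exactly.

## Numerical choices and degenerate inputs

* Constant indicators cannot be min-max standardized (zero range) and are
  refused; a fully constant sample matrix makes the projection objective
  flat — the optimizer warns and returns a direction on the sphere.
* Constant unit surfaces make Moran's I and q undefined (zero variance)
  and are refused.
* Singleton strata are allowed in factor detection (zero within-variance)
  but excluded, with a warning, from pairwise risk tests.
* Permutation p-values are pseudo p-values, `(1 + extreme) / (n_perm + 1)`,
  never exactly zero.
* `run_pipeline()` fans its master seed out as `seed * 10 + stage index`,
  so one integer reproduces the GA, both permutation tests and the
  geodetector byte-for-byte. All study-configuration constants — 999
  permutations, α = 0.05, 500 m units, strata 9/6/2, GA 400/0.8/0.3/200 —
  are configuration defaults, not hard-coded.
* Raster I/O: ESRI ASCII grid is the general-purpose text format
  (georeference and -9999 nodata sentinel preserved). TIFF support is for
  unit-interval surfaces only, with the validity mask carried as a second
  sample, because plain TIFF storage of out-of-range floats is undefined
  in the underlying library; grids read from TIFF fall back to
  `cell_size = 1` with a warning since plain TIFF carries no georeference.

## Known limitations

* One projection direction: multi-directional projection pursuit and other
  optimizers (simulated annealing, PSO) are out of scope.
* Weights schemes are lattice contiguity only — no distance-band or kernel
  weights, no Getis–Ord statistics, no spatial regression.
* The geodetector here covers factor, interaction and risk detection; the
  ecological detector (F-comparison of two factors' within-strata
  variances) is not implemented.
* Area accounting follows the grid: valid cells × cell area. Published
  area tables for real regions often disagree with nominal region extents;
  the package reports grid arithmetic and does not reconcile such
  discrepancies.
* No map-projection handling: grids must arrive co-registered.
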