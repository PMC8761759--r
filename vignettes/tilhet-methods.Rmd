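---
title: "Quantifying spatial heterogeneity of tumor-infiltrating lymphocytes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spatial heterogeneity of tumor-infiltrating lymphocytes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilhet)
```

## The measurement model

`tilhet` works on the output of a multiplex-IHC pipeline: per-cell
coordinates (micrometers, origin top-left, x rightward, y downward, frame
half-open `[0, width) x [0, height)`) with marker scores in `[0, 1]` for
CD3, CD8, FoxP3, CD20, CD45RO and panCK, plus a tissue geometry that
partitions the slide into tumor, stroma and background. Tissue
segmentation (pan-cytokeratin driven, upstream of this package) defines
the compartments; a cell's own panCK score never influences its subset
call, and CD45RO is accepted in input but never analyzed — both mirror how
these panels are used in practice.

**Gating.** Published mIHC studies typically gate predicted marker
expression manually without reporting the gates. We use fixed-threshold
gating (default 0.5; binary 0/1 calls pass through) with a lymphocyte
hierarchy: CD3+ = total T; within CD3+, CD8+ = cytotoxic and FoxP3+ =
regulatory T cells; CD3-CD20+ = B cells. Whether "CD8+" should require CD3
co-expression is a genuinely open choice; we require it (these are
lymphocyte panels, and CD8 is also expressed by some NK and dendritic
cells) and expose `require_cd3_for_cd8 = FALSE` to disable. A CD8+FoxP3+
double positive is tallied in both effector subsets but once as a T cell;
how such cells were tallied in the source analyses is typically unstated,
so this is a documented convention, not a reconstruction.

**Densities and the 0.10 mm² rule.** Compartment densities are
count / exact polygon area, in cells/mm² (1 mm² = 10⁶ µm²; areas by the
shoelace formula, holes as negatively oriented contours). A compartment
smaller than 0.10 mm² yields too unstable a ratio to report: its densities
become `NA`, the exclusion is logged with the sample id, and downstream
statistics drop `NA`s while reporting the effective n. The other
compartment of the same sample is unaffected.

**Boundary precedence.** Point-in-polygon tests use even-odd ray casting.
A cell lying exactly on a shared tumor/stroma edge is assigned to tumor
(tumor > stroma > background), implemented by an explicit
distance-to-edge check for points the ray caster leaves outside.

## Virtual regions and the concordance statistic

To ask "would a TMA core (or a biopsy) have told the same story as the
whole sample?", `k = 4` non-overlapping regions of fixed area are placed
in the tumor compartment of each sample:

* **Areas and shapes.** 0.28 mm² (the cross-section of a 0.6 mm TMA core)
  defaults to a circle; 3.30 mm² (a typical biopsy-scale tumor area)
  defaults to a square. Both are overridable; the shape of the original
  manually selected regions is unknowable, so we pick the shapes of the
  physical analogues.
* **Placement.** Centers are drawn uniformly over the tumor bounding box
  and accepted when the footprint lies in the frame, is disjoint from the
  regions already accepted, and has tumor fraction ≥
  `min_tumor_fraction` (default 0.5 — regions must be *predominantly*
  tumor, small stromal bands allowed). Tumor fractions are exact polygon
  intersections (`polyclip`); circles are matched-area 64-gons, and
  disjointness and frame checks use the polygon's true circumradius so
  footprints never overlap even at the corners.
* **Denominator.** Region density divides by the *nominal* region area,
  not the tumor-only area: stromal bands inside a selected region are
  conventionally counted as part of the tumor compartment. The
  consequence — densities of edge-hanging regions are attenuated by their
  tumor fraction — matters below.
* **Eligibility.** If `k` regions cannot be placed within `max_attempts`
  (default 10 000) candidates, or `k x area` already exceeds the tumor
  area, the sample is INELIGIBLE: a flagged, logged data state rather than
  an error, because dropping small samples is part of the analysis design.
  Larger region areas therefore leave fewer eligible samples.

Eligible samples are classified into quartiles of their mean region
density. Cutpoints are the 25th/50th/75th percentiles by linear
interpolation between order statistics at rank `(n-1)p + 1` (R's default
type-7 quantile) — no percentile definition is canonical here, so we fix
the most common one for bit-reproducibility. Intervals are right-closed
(`(-Inf, Q1], (Q1, Q2], (Q2, Q3], (Q3, Inf)`); boundary values fall to the
lower quartile, and with degenerate equal cutpoints the lowest applicable
quartile wins. Samples, not patients, are the classification unit. The
**correct classification rate** is the percentage of regions whose
quartile matches their own sample's.

### Where the null level of this statistic really sits

Intuition says exchangeable samples (no true between-sample differences)
should give a 25% rate — one in four quartiles. That intuition is wrong
for this statistic: each region is one of the k = 4 values averaged into
its own sample's mean, so under exchangeability a region correlates with
its sample mean at `sd(mean)/sd(region) = 1/sqrt(k) = 0.5`. Simulation
(both an independent matrix-level enumeration and the package's full
spatial pipeline; see the test suite) puts the null rate near **39%** for
k = 4, drifting toward 25% only as k grows or if cutpoints were computed
leave-one-out. Observed rates should therefore be read against a ~39%
chance floor, not 25% — which makes rates in the 60–75% range reported for
real cohorts less impressive than they first appear.

### The region-area effect

For homogeneous Poisson cells, a larger region averages over more cells,
so counting noise shrinks (`CV = 1/sqrt(intensity x area)`) and the
expected rate at 3.30 mm² is at least that at 0.28 mm². The suite verifies
this on cohorts of 12 samples x 20 replicates with lognormal
between-sample intensities (median 150 cells/mm², log-sd 0.5) on a
~36 mm² tumor, requiring regions to be ≥ 95% tumor in both arms. Both are
deliberate study-condition choices: the tumor must be large enough that
four 3.30 mm² regions fit without being forced against the boundary (real
samples eligible for the biopsy-scale analysis are large resections), and
near-contained regions isolate the counting-noise mechanism — with the
default 0.5 cutoff, the nominal-area denominator attenuates edge-hanging
regions by their tumor fraction, a multiplicative noise source that grows
with region size and can mask or even reverse the counting-noise effect.
That interaction is a real property of the estimator worth knowing before
comparing core sizes on tissue with ragged tumor boundaries.

## Cohort statistics

* **Tissue sites.** Kruskal–Wallis (with tie correction, chi-square
  p-value) across sites with ≥ 5 non-missing samples, per subset and
  compartment, with no correction across subsets at this stage; only when
  KW p ≤ 0.05 does Dunn's test run, Bonferroni-corrected within the
  g(g-1)/2 pairwise family and capped at 1. Dunn's z uses pooled mean
  ranks with the standard tie term `sum(t^3 - t) / (12 (N - 1))`; for two
  tie-free groups z² equals the KW H, which the tests exploit as an
  independent cross-check since no Dunn implementation ships with the
  environment's packages.
* **Paired comparisons.** Wilcoxon signed-rank on per-patient averaged
  densities. Zero differences are dropped (a convention; the sources are
  silent), the exact two-sided p is used for n ≤ 25 without tied absolute
  differences, the normal approximation otherwise, and all-zero
  differences return the degenerate p = 1.
* **Replicate averaging.** Multiple samples of one patient in the same
  context are averaged per subset x compartment; missing densities are
  excluded and an all-missing group stays missing.
* **Small chemotherapy cohorts** are summarized descriptively — median
  change, range, number decreased — because formal tests are not
  meaningful at n ≈ 5–9 pairs.
* **Display conventions.** Log-scale figures substitute 0.5 cells/mm² for
  zero densities (5 cells/mm² in region plots) so zeros remain visible;
  substitution never reaches any statistic.

## H-score subtyping

`H = percent_positive x intensity` with percent in [0, 100] and intensity
an integer 0–3 (fractional intensities are rejected rather than silently
accepted), so H ∈ [0, 300]. GATA3/KRT5-6 positivity is H ≥ 20, read as
inclusive; GATA3-only = luminal, KRT5/6-only = basal.

## The synthetic cohort generator

No raw patient data are deposited for this kind of study, so the
generator is first-class, tested code that produces cohorts with the
structure the analysis assumes:

* **Geometry.** A star-shaped tumor nest with radially jittered vertices
  (exact-area rescaling) inside a 3200 x 2800 µm frame, tumor ≈ 3.3 mm²
  (biopsy scale), wrapped by a 200 µm stroma band (an annulus: outer
  contour plus a hole). Infeasible requests (band or blob exceeding the
  frame) error at construction.
* **Point processes.** Homogeneous Poisson (count ~ Poisson(intensity x
  area), uniform by rejection from the bounding box); Thomas cluster
  (Poisson parents, Poisson(µ) offspring per parent, isotropic Gaussian
  dispersion σ; offspring outside the compartment are resampled around
  their parent up to 100 times then dropped, keeping containment exact and
  the realized intensity ≈ parent intensity x µ); gradient Poisson (linear
  intensity trend, by thinning). Defaults: Thomas with µ = 25 offspring
  and σ = 60 µm — lymphocyte aggregates at the scale seen in mIHC images;
  for B cells at low overall intensity this produces sparse dense clusters
  reminiscent of tertiary lymphoid structures.
* **Intensities.** Site multipliers (lymph node 2.2, urinary tract 1.0,
  soft tissue 0.9, liver 0.7, bone 0.3) scale per-subset baselines chosen
  at the scale of published urothelial cohorts (intratumoral CD3/CD8/
  FoxP3/CD20 = 375/140/70/8 cells/mm²; stromal 1250/395/250/125), so
  stroma > tumor for every subset and lymph node > urinary tract > bone.
  Marker co-expression is hierarchical: CD8/FoxP3 are assigned among CD3+
  cells by independent thinning (so marginal intensities match the map and
  double positives occur); CD20+ cells are a disjoint pattern; panCK+
  epithelial cells pad the tumor compartment without entering any
  analysis. Positive/negative marker scores are drawn from [0.7, 1] and
  [0, 0.3], so default gating recovers the generating labels exactly.
* **Cohort design.** ~49 patients with one urinary-tract primary plus a
  Poisson(1.27) number of metastasis samples each (≈ 111 samples), the
  first `n_chemo_pairs = 9` patients contributing pre/post chemotherapy
  pairs whose post sample is scaled by the treatment multiplier (default
  0.6, matching the relative median T-cell decreases reported for
  neoadjuvant cohorts). One root seed expands to per-sample child seeds
  via a fixed linear congruential scheme, making whole cohorts
  byte-reproducible.

**What the generator does not emulate:** per-sample variance components of
any real cohort (none are published — effect sizes here are chosen for
testability), irregular multi-nest tumor architectures, necrosis, TLS
follicle geometry, staining artifacts, or segmentation errors. Passing
tests therefore demonstrate that the estimators and statistics behave
correctly on data with the assumed structure, not that any biological
conclusion transfers to real tissue.

## Numerical choices and problem sizes

Polygon intersections and disjointness checks run through `polyclip`
(integer-scaled exact clipping); region disjointness is asserted to
1e-6 mm². Rasterized cross-checks use mid-pixel grids (0.5 µm/pixel by
default, evaluated in row blocks to bound memory). The test suite sizes
its simulations to run in a few minutes on one CPU: 200 replicates for
Poisson calibration and density recovery (3-standard-error bands), 200
exchangeable samples for the null concordance level, 20 replicate cohorts
for the region-area effect, 200 null cohorts of 30 samples for the
Kruskal–Wallis type-I error (expected within 5% ± 3 points at α = 0.05),
and 2000 placements for the center-uniformity chi-square.

## Known limitations

* The stroma band is a single annulus; real stroma is interleaved with
  tumor nests. Region tumor fractions on real geometries will be more
  variable than on synthetic ones.
* Rate comparisons between region areas inherit the nominal-area
  attenuation effect described above whenever regions may hang over the
  tumor boundary.
* GeoJSON I/O covers the FeatureCollection/Polygon subset this package
  writes (one polygon with holes per compartment feature); it is not a
  general GeoJSON reader.
* Exact Wilcoxon p-values are unavailable with tied absolute differences
  (the normal approximation is used), matching standard practice.
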