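---
title: "Methods: OCT retinal morphology phenotyping with octmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: OCT retinal morphology phenotyping with octmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octmorph)
```

`octmorph` chains five stages: synthetic data generation, boundary
segmentation, scan/cohort quality control, phenotype derivation, and the
statistical models (per-variant association and two-sample Mendelian
randomisation). This vignette records the models, the parameters that
matter, and the numerical and design choices behind each stage.

## The synthetic retina

Real macular OCT cohorts are access-restricted, so the package carries its
own generative model, used both as a first-class simulator and as the
ground truth for every test. Total retinal thickness over the scanned field
is a radially symmetric pit-and-rim surface,

$$T(r) = P + A\,e^{-(r-R)^2 / (2 (R/2)^2)} - D\,e^{-r^2 / (2 w^2)},$$

with plateau $P$ (default 300 µm), pit depth $D$ (75 µm) and width $w$
(0.6 mm), and a parafoveal rim of amplitude $A$ (20 µm) at radius $R$
(1.5 mm). The two Gaussians are not a biophysical claim; they are the
simplest smooth shape with separately controllable foveal and diffuse
components, which is exactly the contrast the downstream analysis needs:
*foveal* variants act on $D$ (a shallow pit is the mild foveal-hypoplasia
phenotype), *diffuse* variants act on $P$. The constraint $P - D > 0$ keeps
central thickness positive. Defaults are plausible for adult maculae but
deliberately uncalibrated — no public distributional reference exists for
the cohorts this emulates, so they were chosen once and are not tuned.

Volumes are rendered at a desk-scale raster of 64 B-scans × 64 A-scans ×
256 depth voxels over 6 × 6 mm (clinical hardware scans 128 × 512; the
raster is configurable) with an axial voxel of 3.5 µm, a plausible
spectral-domain scale. Each A-scan gets a bright band at the ILM and at the
BM. Two choices matter:

* **Band width equals the segmentation's running-median window (15
  voxels).** A median filter of width $k$ preserves exactly the extent of a
  plateau at least $k$ wide and erases anything much narrower. Matching the
  two widths makes the noiseless pipeline *exact* — the detected
  point-of-interest region coincides voxel-for-voxel with the rendered band
  — which turns "segmentation recovers truth" into a sharp, testable
  invariant instead of a tolerance.
* **Bands decay linearly from the truth boundary voxel** (peak at the ILM's
  inner edge and the BM's outer edge), so the brightest voxel of each band
  is the boundary itself and the surface has an unambiguous sub-band
  definition.

Artifacts are injected mechanically, not physically: blinks suppress bands
over contiguous B-scans, motion shifts whole B-scans axially (truth moves
with them), and z-clipping pushes boundary positions out of the depth range
and invalidates their truth. There is no speckle, no layer-by-layer
reflectivity, no disease progression — passing tests show the *algorithms*
behave as specified, not that they would segment pathological clinical
scans.

Cohorts draw covariates (age, sex, weight, height, machine id, genetic
PCs), Hardy–Weinberg dosages, per-eye surface parameters with genotype and
covariate effects, correlated between eyes via a shared/specific noise
split ($\sqrt{\rho}\,z_\text{participant} + \sqrt{1-\rho}\,z_\text{eye}$,
$\rho = 0.8$ by default), LogMAR acuity and a latent pigmentation score
binned into four ordinal hair colours (red hair is a separate flag so the
exclusion rule is exercisable), glaucoma labels with a mean GCC deficit
(label-only — enough to exercise the rank-sum contrast, not a disease
model), and QC indicators degraded by the artifact flags.

## Segmentation

Per A-scan: running median (window 15 voxels, odd, shrinking symmetrically
at the edges so the output length matches and window 1 is the identity);
points of interest are indices with $|x_i - \mathrm{median}(x)| > 2\,
\mathrm{sd}(x)$, where both statistics are taken over the smoothed profile
(the only vector in scope) and sd is the population form; the extreme
indices of the set are labelled ILM (vitreous side, per the
`depth_orientation` flag, default `inner_high`) and BM. The inequality is
strict, fixed for testability; a zero-variance profile yields no points and
the A-scan is flagged invalid, never an error. Fewer than two points of
interest also flags the A-scan. The window default suppresses speckle-like
noise while preserving bands; it is configurable, as is everything
downstream of it.

The composite surfaces are cleaned row-wise (along the A-scan axis) with a
Hampel-type rule: a position is an outlier when it deviates from the
sliding-window median (11 positions) by more than $3 \times \max(\mathrm{MAD},
0.5)$ voxels, where the MAD is computed within the same window. The
window-local MAD is the crucial choice: a row-global MAD flags the genuine
foveal dip as an outlier whenever the raster is coarse, while the local
form inflates the threshold exactly where the surface genuinely curves.
The 0.5-voxel floor reflects quantisation — boundaries are integer voxels,
so sub-half-voxel deviations are never outliers — and makes the filter
idempotent in practice. Outliers and invalid positions are linearly
interpolated from valid neighbours (nearest-valid at row edges); rows with
fewer than two anchors stay invalid. A second, column-wise pass fills rows
that are wholly invalid (blinks) from neighbouring valid rows, producing a
composite surface over the whole raster — this is what lets the ILM edge
indicator see the near-zero gradient across blink-suppressed B-scans. The
per-A-scan loop is compiled (Rcpp); a test asserts it equals the plain R
path position by position.

Thickness is $|ILM - BM| \times$ axial voxel size — the absolute distance,
so the map is invariant under flipping the depth convention. Whether the
reference measurements use signed or absolute distance is not documented
anywhere we could follow; absolute is the defensible default.

Raster resolution bounds what segmentation-plus-cleaning can recover: at
16 × 16 the pit spans ~2 A-scans and is statistically indistinguishable
from an outlier spike, so the outlier pass rounds it off. From 24 × 24
upwards (and at the 64 × 64 default) noiseless recovery is exact; tests
pin this.

## Quality control

The scan indicators follow their operational definitions: ILM indicator =
minimum over valid positions of the absolute central-difference axial
gradient at the (rounded) ILM depth, one-sided at volume borders, 0 when
nothing is valid; valid count = fraction of positions with both boundaries
valid and at least `margin_voxels` (5) from either depth end; motion
indicators = over consecutive B-scan pairs and two layers (nerve fibre and
full thickness — when no sublayer table is supplied the full profiles stand
in for both and the output says so), the minimum Pearson correlation, the
maximum mean absolute difference (µm), and the maximum of mean absolute
difference divided by the pooled mean thickness of the pair. That last
normalisation is our own (the indicator is named in the field without a
formula); dividing by the pooled mean makes it scale-free. A zero-variance
profile in a pair contributes correlation 0 and a flag rather than NaN.

Scan removal: image quality < 45 (strict), plus, independently per
segmentation indicator, the poorest 20% of the input population (lowest for
ILM indicator, valid count, minimum motion correlation; highest for the two
motion difference indicators); removals are unioned and each triggering
rule is recorded. Ties at the percentile cut are *retained* (strictly-poorer
removal), so with distinct values each rule marks exactly
$\lfloor 0.2N \rfloor$ scans and the whole decision is reproducible. The
percentile population defaults to the full input table; a
`percentile_population = "post_quality"` mode restricts it to scans that
passed the score cut, since the reference description can be read either
way.

Cohort filters: refractive error is `spherical + 0.5 × cylindrical`
dioptres; the outlier rule defaults to $|x - \mathrm{median}| > 1.5 \times
IQR$ with an optional additive sd slack — the published phrasing of this
rule cannot be parsed uniquely, so both constants are exposed and the
closest standard rule is the default. PC-space filtering keeps participants
within a (boundary-inclusive) Euclidean radius of the PC1–PC2 centroid,
given absolutely or as a distance quantile. Kinship filtering takes
relationship pairs as input (as biobanks provide them), keeps pairs of
degree ≤ 3, and greedily deletes the most-connected node until no edge
remains, breaking ties by deleting the lexicographically smallest id —
deterministic, and the retained set provably induces no edges.

## Phenotypes

The Macula 6 grid is configurable geometry: a central exclusion circle
(radius 0.5 mm) and superior/inferior halves of three concentric zones
(outer radii 1.5 and 3 mm, the outer zone running to the field corners).
The published grid's exact geometry is defined in a source we do not
reproduce; this layout honours its structure (six included subfields,
central field excluded from the overall mean) and any other can be
substituted via the constructor. Subfield means are over valid raster
points; the overall mean is point-weighted over the six included regions.

Per-eye traits are adjusted by OLS on refractive error plus the technical
indicators, with the adjusted value defined as residual + sample mean so
scale and mean survive; collinear columns are dropped with a warning. Eyes
are then averaged, with a single available eye used as-is (the reference
analysis had most participants imaged in both eyes and does not state its
missing-eye rule; the available-eye mean is the least-destructive choice).

Central foveal thickness: cubic smoothing splines (GCV-chosen smoothing by
default, fixable via `spar` for exact reproducibility) are fitted to the
central row and central column of the map — the cross-sections nearest the
field centre, lower index on ties — with invalid points linearly
interpolated first; the phenotype is the mean of the two splines evaluated
at the field centre (0 mm). "Midpoint of the two cross-sectional vectors"
could alternatively mean a crossing-point value; the two-spline mean is
implemented as the natural symmetric reading. Constant profiles short-cut
to the constant (a degenerate case smoothing splines dislike). Left eye is
the default map eye, following the reference convention.

Genotype-stratified maps average per-participant maps pointwise within
dosage groups 0/1/2 and report het − ref and alt − ref difference matrices
with group sizes; an empty group yields missing outputs with a warning.
`diff_map_peak()` locates the absolute extremum — near the centre for
foveal variants, nowhere in particular (and flat: point-wise sd well under
20% of the mean) for diffuse ones.

## Association models

Everything is ordinary least squares via `stats::lm` (or its exact
residualised equivalent): trait on dosage plus covariates, with two-sided
p-values from the t distribution (exact at small n, indistinguishable from
normal at cohort n). Machine id and other categoricals are treatment-coded
with the most frequent level as reference. Fractional (imputed) dosages are
accepted wherever hard calls are. Monomorphic variants give an NA row with
a warning — a scan over thousands of variants should not abort. The
many-variant scan projects covariates out of trait and dosages once
(Frisch–Waugh–Lovell) and is tested to match the full per-variant fits to
machine precision. The dosage×sex interaction model reports the interaction
term; an all-one-sex sample is an error, not an NA.

The min-P meta combination across the two layer traits is exactly the
elementwise minimum — a ranking/selection device, deliberately *not* a
calibrated test: the reference pipeline's trait-covariance weighting
(MTAG-style) is out of scope and the documentation says so. Locus grouping
is single-linkage chaining per chromosome with a 1.5 Mb gap; Bonferroni and
genome-wide (5 × 10⁻⁸) masks are strict inequalities. The Bonferroni
denominator for each secondary analysis is the size of the variant set
actually tested. Ordinal pigmentation models drop an exclusion category
(red hair) before fitting; visual acuity models take the better-seeing eye
(lower LogMAR). The glaucoma GCC contrast is `stats::wilcox.test`
(normal approximation with continuity and tie correction); exact
enumeration is reserved for test oracles at n ≤ 10.

## Mendelian randomisation

Instruments are genome-wide-significant variants thinned by a greedy
per-chromosome distance window (10 Mb, keep the lowest p, drop the rest,
repeat). This is a stand-in for LD clumping — no LD reference panel ships
with the package — and is documented as such; both constants are explicit.
Harmonisation intersects on variant id, flips outcome betas whose effect
allele is the exposure's other allele, drops irreconcilable rows with a
reason, and drops palindromic (A/T, C/G) variants by default since strand
cannot be resolved without frequencies; retention is a flag when
frequencies are available.

IVW is the fixed-effect form, $\hat\beta = \sum w_j \beta_{Xj} \beta_{Yj} /
\sum w_j \beta_{Xj}^2$, $w_j = se(\beta_{Yj})^{-2}$, normal p-values; an
optional multiplicative random-effects scaling inflates the SE by
$\max(1, \sqrt{Q/(k-1)})$ when heterogeneity warrants (which flavour the
reference used is unstated, so the choice is an explicit argument). A
single instrument is permitted only behind `allow_single` (Wald ratio).
MR-Egger orients exposure effects positive, then fits weighted least
squares with an intercept; slope = causal estimate, intercept = directional
pleiotropy, t-distribution p-values on $k - 2$ df, minimum three
instruments. The simulator treats exposure effects as measured without
error — the no-measurement-error assumption under which both estimators are
derived; adding exposure-side noise induces the classical regression
dilution, which is real two-sample-MR behaviour but would make "unbiased
recovery" the wrong invariant to test. Swapping the exposure and outcome
arguments runs the reverse-direction analysis unchanged.

## Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` use desk-scale sizes chosen to
make Monte-Carlo checks sharp while staying light: 50 rendered volumes at
64 × 64 × 256 for segmentation exactness (noise sd at 10% of band
contrast for the robustness half), 1,000-scan QC tables, 2,000-participant
cohorts for phenotype recovery (10 µm/allele foveal, 5 µm/allele diffuse),
1,000 null variants at n = 1,500 for type-I calibration plus a 2 µm/allele
recovery at n = 5,000, and 200 replicate summary studies of 50 instruments
for MR calibration. Every stochastic operation is a pure function of its
config and seed: seeds thread through `--seed` in the acceptance script,
and repeated calls are byte-identical (tested).

## Limitations

* The generator's smooth two-Gaussian surface cannot produce pathology
  (oedema, atrophy, detachment) or realistic speckle; segmentation accuracy
  on clinical images is untested here by construction.
* Intra-retinal sublayer boundaries (RNFL/GCIPL internals) are out of
  scope; sublayer thicknesses enter as tabular inputs where needed.
* Distance-based instrument pruning ignores actual LD structure.
* The min-P combination is a selection heuristic, not a calibrated
  meta-analysis.
* Kinship degrees are taken as given; no relatedness estimation from
  genotypes is performed.
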