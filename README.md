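# octmorph

Retinal morphology phenotyping from macular optical coherence tomography
(OCT), end to end: surface segmentation, scan quality control, foveal
phenotype derivation, genetic association, and two-sample Mendelian
randomisation — with a synthetic-data module that generates ground-truthed
inputs for every stage, so the whole pipeline is testable without
access-restricted cohort data.

## The problem

The macula has a valley-like morphology: the inner retinal layers (retinal
nerve fibre layer, RNFL; ganglion cell inner plexiform layer, GCIPL) taper to
nothing at the fovea. Population imaging cohorts capture this with macular
volume scans (raster of B-scans, each a row of axial A-scans), and thickness
phenotypes derived from those scans — Macula 6 grid means of inner layers,
total retinal thickness at the central fovea — are heritable, clinically used
biomarkers (e.g. ganglion cell complex thickness, GCC = RNFL + GCIPL, in
glaucoma). `octmorph` implements the analysis chain for such studies:

1. **Segmentation.** For each A-scan intensity profile *x*, smooth with a
   running median; flag *points of interest* `{i : |x_i − median(x)| > 2 sd(x)}`;
   the extreme indices of that set are the inner limiting membrane (ILM,
   vitreous side) and Bruch's membrane (BM). Composite surfaces are cleaned
   with a Hampel-style sliding-median/MAD outlier interpolation, and total
   retinal thickness is `|ILM − BM| × axial voxel size`.
2. **Quality control.** Scan indicators — ILM indicator (minimum localised
   edge strength at the ILM), valid count (unclipped fraction), and motion
   indicators from Pearson correlations and mean absolute differences between
   consecutive B-scan thickness profiles — with removal of scans scoring
   below an image-quality cut (45) and, per indicator, the poorest 20% of the
   population. Cohort filters: spherical-equivalent refractive error
   (`sph + 0.5 cyl`) outliers, genetic-PC distance, and greedy kinship
   pruning.
3. **Phenotypes.** Macula 6 grid subfield/overall means (central field
   excluded); per-eye covariate regression (residual + mean) before
   left/right averaging; central foveal thickness as the midpoint value of
   cubic smoothing splines fitted to the two central cross-sections; and
   genotype-stratified mean thickness maps with het−ref / alt−ref difference
   matrices.
4. **Association.** Additive linear models of trait on allele dosage
   (0/1/2) with covariates, a fast residualised scan for many variants,
   dosage×sex interactions, ordinal pigmentation models, better-eye LogMAR
   acuity models, min-P meta combination across two traits, 1.5 Mb locus
   clustering, Bonferroni/genome-wide thresholds, and a Wilcoxon rank-sum
   GCC contrast.
5. **Mendelian randomisation.** Instrument selection (P < 5×10⁻⁸ plus
   distance pruning), allele harmonisation, and the two standard estimators:
   fixed-effect IVW, `β̂ = Σ wⱼ βXⱼ βYⱼ / Σ wⱼ βXⱼ²` with `wⱼ = 1/se(βYⱼ)²`,
   and MR-Egger (weighted regression with an intercept estimating directional
   pleiotropy).

The synthetic-data module simulates all of it: pit-and-rim thickness
surfaces `T(r) = P + A e^{−(r−R)²/(2(R/2)²)} − D e^{−r²/(2w²)}`, rendered OCT
volumes with bands at the true surfaces plus blink/motion/clipping
artifacts, Hardy–Weinberg genotypes with foveal or diffuse thickness
effects, covariates, acuity and pigmentation traits, and MR summary
statistics with known causal effect and pleiotropy.

## Worked example

```r
library(octmorph)

params <- retina_surface_params(pit_depth_um = 75)   # 75 um foveal pit
map <- simulate_thickness_surface(params)            # 64 x 64 over 6 mm
rendered <- render_oct_volume(map, noise_sd = 19, seed = 42)
surfaces <- segment_volume(rendered$volume)
derived <- thickness_from_surfaces(surfaces)

macula6_mean(derived)
#> # A tibble: 7 × 3
#>   region          mean_um n_points
#> 1 superior_inner     299.      350
#> 2 superior_middle    311.     1154
#> 3 superior_outer     301.      500
#> 4 inferior_inner     299.      350
#> 5 inferior_middle    311.     1154
#> 6 inferior_outer     301.      500
#> 7 overall            306.     4008

central_foveal_thickness(derived)   # 228.2 um; generator truth is 227.7 um
```

The Macula 6 means show the parafoveal rim (middle zone ≈ 311 µm) against
the ≈ 300 µm plateau, and the spline-derived central foveal thickness lands
within half a micrometre of the generating surface despite intensity noise
at 10% of band contrast. A two-sample MR run on simulated summary
statistics:

```r
s <- simulate_mr_summary(50, causal_effect = 0.5, seed = 42)
inst <- harmonise_instruments(s$exposure, s$outcome)
ivw_estimate(inst)
#> <mr_estimate> IVW: slope 0.5088 (se 0.0343, p 8.01e-50), k = 50
egger_estimate(inst)
#> <mr_estimate> Egger: slope 0.3080 (se 0.1126, p 0.0087), k = 50
#>   intercept 0.0431 (se 0.0232, p 0.0696)
```

IVW recovers the true causal effect 0.5; the Egger intercept is compatible
with zero, as expected with no injected pleiotropy (single-study Egger
estimates are noisy — its calibration is checked over replicates in the
acceptance script). `autoplot()` methods draw thickness maps, stratified
difference maps and MR scatter plots; `tidy()`/`glance()` return tidy
coefficient tables.

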