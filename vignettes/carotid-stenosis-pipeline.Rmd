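---
title: "Methods: cascaded carotid lumen segmentation and NASCET stenosis quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cascaded carotid lumen segmentation and NASCET stenosis quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Extracranial carotid stenosis is graded from the geometry of the arterial
lumen: the NASCET criterion compares the minimum lumen diameter (MLD) at the
narrowest point of the internal carotid artery (ICA) with a reference vessel
diameter (RVD) from a normal segment,

$$\mathrm{percent} = \Bigl(1 - \frac{\mathrm{MLD}}{\mathrm{RVD}}\Bigr)\times 100,$$

with mild ($\le 30\%$), moderate ($30\%<p\le 70\%$) and severe ($>70\%$)
classes; complete occlusion (100%) is excluded, mirroring the usual exclusion
of occluded arteries from such cohorts. Automating this measurement from
black-blood neck MRI is hard for one structural reason: the lumen occupies
well under 0.1% of the image grid. `carotidseg` implements a three-stage
pipeline built around that imbalance:

1. **Localization** — a 2D U-Net over cross-sectional slices predicts a
   region of interest (ROI) around the artery; a crop box is derived from it.
2. **Segmentation** — a residual-encoder 3D U-Net segments the lumen inside
   the crop, trained on random patches, with five-fold cross-validation and
   fold ensembling.
3. **Quantification** — the binary lumen is reduced to a centerline,
   straightened by curved planar reformation, profiled slice-by-slice in
   area, and graded by the NASCET formula.

Because real multicenter HR-MRI with expert lumen labels cannot be shipped,
the package includes a first-class synthetic phantom generator that emulates
the geometric and statistical structure the pipeline relies on; every stage
is exercised end-to-end on phantoms.

## The phantom generator

`phantom_spec()`/`generate_phantom()` build an analytic Y-tree: a common
carotid artery (CCA, radius 3.0 mm by default) that bifurcates into an ICA
(2.4 mm) and an external carotid artery (ECA, 1.8 mm), 50 mm per branch, on
a 192 x 352 x 352 grid with anisotropic 0.59 x 0.46 x 0.46 mm voxels — the
spacing all volumes are resampled to before the networks see them. A voxel
is lumen iff its center lies inside the analytic tube (an unbiased, easily
re-implemented membership rule); tube ends are flat-capped. With these
defaults the labeled fraction computes to about 0.096% of the grid,
respecting the sub-0.1% occupancy regime by construction.

Focal stenoses are parametric: over a window of `length` mm the branch
radius follows a cosine taper down to
$(1-\mathrm{percent}/100)\cdot r_\mathrm{branch}$ at the throat and back.
The taper is smooth and differentiable and preserves the analytic throat
radius, so every phantom carries exact ground truth (true percent, MLD, RVD,
throat position, centerline points).

Image contrast follows black-blood T1 imaging: a dark lumen (20 a.u.)
inside a brighter 1 mm wall ring (120 a.u.) on mid-intensity background
(60 a.u.), plus additive Gaussian noise (sd 8 a.u.). The noise-free image
restricted to the lumen equals the lumen intensity exactly, which the test
suite uses as an invariant. What the phantom does **not** emulate: MR
physics (coil profiles, bias fields, flow artifacts), plaque components,
vessel-wall labels, and anatomical variation beyond radius/angle jitter.
Passing phantom tests therefore demonstrates that the pipeline machinery is
correct, not that the shipped desk-scale networks would transfer to clinical
data.

Cohorts (`generate_cohort()`, `memory_cohort()`) allocate grades by
largest-remainder rounding of a requested mix; the default mix is the
grade composition of a 545-lesion training-validation cohort
(3 mild : 206 moderate : 336 severe). Each lesion receives one ICA stenosis
with a grade-banded target percent, mild geometric jitter (bifurcation angle
±5°, radii ±10%), a scanner-style tag, and a derived per-lesion seed, so
cohorts are bit-reproducible.

## Preprocessing and the localization target

Volumes are resampled to 0.59/0.46/0.46 mm (trilinear for images, nearest
for labels) and z-score normalized with the population standard deviation
(constant volumes map to zero). The localization *target* is not the lumen
but an inflated ROI: per slice, the labeled-pixel centroid defines the ROI
center and the disk radius is

$$r = (1+\epsilon)\sqrt{\frac{l\,w\,N}{\pi}},$$

i.e. $(1+\epsilon)$ times the equivalent-circle radius of the slice's
labeled area ($l, w$ the in-plane pixel dimensions in mm, $N$ the labeled
pixel count). This is the only dimensionally consistent reading of the
inflation rule, and it makes $\epsilon = 1$ exactly double the $\epsilon = 0$
radius. The disk is rasterized with the same pixel-center rule as the
phantom and **unioned** with the original labels, so inflation can never
lose a labeled pixel; whether the source design unions or replaces is not
stated, and the union is the conservative choice. Default $\epsilon = 0.5$:
a generous margin while keeping the ROI small.

Augmentation covers the usual volumetric families (in-plane rotation ±30°,
scaling 0.7–1.4, per-axis flips, Gaussian noise and smoothing, intensity
scaling, gamma contrast); the families are fixed, the ranges are ordinary
volumetric-segmentation practice and fully configurable. Spatial transforms
hit image and label identically (label nearest-neighbor); intensity
transforms hit the image only; a seed reproduces the draw bit-identically.

## The networks and their training

Both networks are built by a compact, self-contained U-Net engine written
for this package: direct im2col+GEMM convolutions (through the system BLAS)
with hand-derived backward passes, instance normalization, leaky-ReLU,
strided-convolution or average-pooling downsampling, transposed-convolution
upsampling, skip connections, and per-resolution deep-supervision heads
whose losses halve with depth (normalized to sum 1). Every gradient is
verified against central finite differences in the test suite.

The **paper profile** mirrors the reference architecture scale: the 2D
localization net has 8 encoder / 7 decoder stages (two conv+norm+activation
per stage), the 3D net a residual encoder of 6 stages / 5 decoder stages,
base 32 channels doubling to a 320 cap, average pooling in the first block
of stages 2–3, batch sizes 12 (2D) and 4 (3D), 1000 epochs, SGD with
Nesterov momentum 0.99, initial learning rate 0.01 under polynomial decay
$lr(e) = 0.01\,(1-e/1000)^{0.9}$, and an equally weighted BCE + Dice loss.
Patches of 128 x 192 x 192 (4 per ROI) feed the 3D stage. Undisclosed layer
details (normalization flavor, activation, down/upsampling operators,
channel schedule, deep-supervision weights, which stages pool) follow
common practice for this family of segmentation networks and are all
configurable.

The **desk profile** is the package's own scaling of the same design to one
CPU: 64 x 96 x 96 phantoms, 4-stage nets with base 4 channels (capped at 32),
one residual block per stage, 15 epochs, 2 patches of 24³ per volume, and a
2x mean-pooled slice resolution for the localization stage. Pooling the 2D
stage is justified by its job: it only has to place a generous crop box
(margin 8 voxels), so halving the in-plane resolution costs nothing
measurable while cutting its cost fourfold. The predicted ROI is restricted
to its largest connected 3D component before the box is taken — a union
bounding box is otherwise destroyed by a single stray false-positive pixel.
If localization yields no ROI, an explicit condition is raised; the
experiment driver falls back to the uncropped volume.

Cross-validation splits are stratified by grade and scanner tag with a
round-robin deal inside each stratum; fold models are combined by averaging
voxelwise probabilities and thresholding at 0.5 (the ensembling rule is not
specified beyond "ensemble"; probability averaging is the standard choice).
Whether the two networks are optimized jointly or sequentially is left open
by the source; the cascade here trains them sequentially with the
localization stage frozen, which is the interpretation implemented and
tested.

## Stenosis quantification

`extract_centerline()` re-implements geometric centerline extraction rather
than delegating to external vascular-modeling software: an exact Euclidean
distance transform gives each foreground voxel its medial depth; Dijkstra
paths over the 26-connected foreground graph with edge cost
$\mathrm{len}/(\mathrm{depth}+0.5)^2$ hug the medial axis; endpoints come
from geodesic eccentricity, the third branch from the voxel farthest from
the main path, and the bifurcation from where that branch meets it. The
common trunk is the branch descending below the bifurcation along the slice
axis (feet-to-head slice order is assumed); of the two distal branches the
ICA is the one with the larger caliber, judged on the **distal 40%** of each
arm (minus a 2 mm tip guard). Judging caliber distally matters: a severe
focal stenosis near the bifurcation would otherwise demote the true ICA
below the ECA and swap the labels. With no side branch longer than 5 mm the
tree degenerates to a single branch, labeled ICA so diameter measurement
still applies.

`straighten()` performs curved planar reformation: square planes (64 pixels
at 0.3 mm) orthogonal to the centerline tangent, carried by parallel
transport to avoid twist, sampled nearest-neighbor, every 0.5 mm of arc
length. Each plane is restricted to the in-plane connected component at its
center: near the bifurcation an orthogonal plane also slices the sibling
branch, which must not count toward this branch's area. If a mid-branch
component touches the plane border the plane is enlarged once (doubled) with
a warning. The area profile is pixel count x pixel area, smoothed by a
3-plane moving average within each branch; diameters are equivalent-circle
diameters $d = 2\sqrt{A/\pi}$ — rotation-invariant and consistent with an
area-based profile.

MLD is the diameter at the minimum of the smoothed ICA profile, excluding
2 mm after the bifurcation (flow-divider artifact) and 2 mm at the distal
end; ties resolve to the most proximal plane. Two RVD strategies ship,
because the literal "dilated portion" phrasing conflicts with the standard
NASCET denominator (normal distal ICA): `distal_ica` (default) takes the
median diameter over the distal ICA window, `bulb_max` the maximum near the
bifurcation. On a near-constant vessel the median can fall a hair below the
measured MLD; the report then raises RVD to MLD so `mld <= rvd` always
holds and the percent reads 0. A measured percent is capped at 99.999
rather than 100: voxel dropout at a sub-voxel throat cannot certify an
occlusion, which is out of scope.

### Resolution limits, and how the tests choose phantom spacing

A 90% stenosis of a 2.4 mm-radius ICA has a throat diameter of 0.48 mm —
about one voxel at the scanner-like 0.46 mm in-plane spacing. No area-based
measurement on a binary mask can resolve that to a few NASCET points: the
throat plane holds 0–2 voxels and the quantization error alone spans tens
of points. The parameter-recovery suite therefore voxelizes its phantoms at
0.4/0.25/0.25 mm, where the throat spans ~2 voxels and quantization
contributes only ~1.5 points; this is a property of sampling theory, not a
tuning decision, and the phantom generator's defaults are unchanged. At that
resolution the recovery error across targets 20–90% stays within ±5 points,
with a mild systematic underestimate (~1–3 points) contributed by the
3-plane smoothing at the throat.

## Evaluation statistics

Segmentation quality: Dice, IoU, absolute relative volume error,
voxel-level sensitivity, specificity, ASSD and HD95. Surfaces are boundary
voxels by 6-connectivity face exposure (volume border counts as exposed);
nearest surface distances come from the exact anisotropic Euclidean
distance transform, ASSD is the mean and HD95 the 95th percentile of the
pooled symmetric distance multiset. These are the standard definitions,
adopted because the source's exact conventions are not published; the tests
pin them to a brute-force all-pairs oracle. Specificity is computed on the
union bounding box plus margin — on a full neck grid the background
dominance pins it at 1.0 and the number carries no information. Sensitivity
is voxel-level recall (the surface-based alternative is a plausible but
less common reading).

Diagnostic metrics for the severe/non-severe decision use the 2x2
definitions with AUC as the Mann-Whitney rank statistic over the continuous
measured percent. Agreement: Lin's concordance correlation with population
moments and a z-transform confidence interval using Lin's asymptotic
variance; ICC(A,1) (two-way random, absolute agreement, single measure)
with the McGraw-Wong F-based interval. The Wilcoxon signed-rank test drops
zero differences, uses average ranks, enumerates the exact tie-aware null
for n <= 25 (convolution over doubled ranks) and a tie-corrected,
continuity-corrected normal approximation beyond; significance is flagged
at 0.05. Mild and moderate lesions merge into "non-severe" for the
two-class task, reflecting both the scarcity of mild lesions and the
clinical contrast that matters.

## Problem sizes and reproducibility

The shipped experiment scale is deliberate: 12 phantoms of 64 x 96 x 96,
five folds, 15 epochs — the `desk` profile — so that the full cascade,
its no-localization ablation, and the quantification suite all run on a
single CPU in minutes. The same code paths accept the `paper` profile
unchanged. All randomness flows from explicit integer seeds: phantom noise,
cohort jitter, weight initialization, batch order, patch corners and
augmentation draws; re-running any stage with the same seed reproduces its
outputs bit-identically (floating-point reductions are deterministic on a
fixed BLAS).

Known limitations worth stating plainly: the desk networks are far below
the capacity needed for clinical images; the phantom's intensity model is a
caricature of MR contrast; centerline branch labeling assumes a Y-topology
with feet-to-head slice ordering; the straightening step measures areas on
a binary mask, so sub-voxel throats are resolution-limited as discussed;
and the DSA reference procedure, manual annotation workflow and
multicenter benchmark results are intentionally out of scope.
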