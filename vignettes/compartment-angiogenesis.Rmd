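---
title: "Compartment-resolved quantification of tumour angiogenesis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartment-resolved quantification of tumour angiogenesis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselquant)
```

## The measurement problem

Tumour angiogenesis in breast-cancer sections is classically scored by
microvessel density in visually selected hot spots, which is sensitive to
observer choice. The approach implemented here instead measures the
**relative endothelial area** (REA) in pathologist-defined circular regions
of interest, each assigned to one of three tumour compartments:
tumour-associated stroma (TAS), tumour parenchyma (T), and the invasive
front (IF). For one compartment of one patient,

$$\mathrm{REA}\,[\%] = 100 \cdot \frac{EA}{AA},$$

where $EA$ is the physical area (mm²) of CD34/DAB-positive endothelium
inside the compartment's ROIs and $AA$ is the total analyzed (ROI) area.
Everything upstream of that ratio — virtual-slide assembly, stain
unmixing, thresholding, object validation — exists to make $EA$
reproducible and auditable.

Because the pipeline consumes whole-slide images and patient tables that
cannot be redistributed, the package carries a synthetic-slide and
synthetic-cohort generator with exact ground truth; every stage is tested
against that ground truth.

## Virtual-slide assembly

Slides are acquired as overlapping camera tiles. Three corrections are
applied before any measurement:

* **Flat-field shading compensation.** Each tile is divided by a
  non-saturated white reference and rescaled to the background target
  (235 on all channels by the acquisition convention):
  $I'_c(x) = I_c(x)\, t_c / W_c(x)$, rounded and clipped to [0, 255].
  The white image is acquired per scanning session, so the vignette is a
  per-camera-field property and the same reference applies to every tile.
* **Overlap registration.** Stage positioning is accurate to a few
  micrometres, so each tile is realigned against its left (or upper)
  neighbour by maximizing normalized cross-correlation of the grayscale
  overlap content over integer shifts within ±8 px. Correlation is
  evaluated on a central patch of the overlap (up to 256 px per side),
  which bounds cost without hurting the integer-peak location. If the best
  correlation is below 0.2 the overlap is considered featureless (blank
  background), the nominal offset is kept and the fallback is flagged.
  Registration is integer-pixel only: the stage error is ~3 px at the
  default scale and subpixel interpolation would blur the intensities that
  the OD threshold later consumes.
* **Stitching.** Tiles are placed at their refined offsets; in overlaps
  the pixel comes from the tile whose centre is nearer (ties keep the
  earlier-placed tile). This single-coverage seam rule guarantees that
  area measurements never count a pixel twice and avoids blending
  artefacts that would bias thresholding.

## Stain separation

Brightfield intensities are converted to optical density per channel,
$OD_c = -\log_{10}(I_c / I_{0,c})$, with intensities floored at 1 (finite
OD), OD clipped below at 0 and capped at 3 (beyond the camera's dynamic
range). Under Beer–Lambert, OD is linear in stain amount, so a pixel is
modelled as

$$OD(x) = a_H(x)\, s_H + a_D(x)\, s_D,$$

with unit-norm OD stain vectors $s_H$ (Hematoxylin) and $s_D$ (CD34-DAB)
and non-negative abundances. Unmixing solves the two-variable
non-negative least-squares problem per pixel in closed form: the
unconstrained solution is used when feasible, otherwise the optimum lies
on a boundary of the quadrant and the better of the two single-stain fits
is taken (exact for a convex two-variable problem; verified against a
dense grid search in the tests). The per-pixel residual norm is kept as a
map: a third unexplained chromogen shows up there instead of being
silently absorbed into the two abundances.

Stain vectors are trained from user-indicated pixels (at least 10 per
stain). The base estimate is the normalized mean OD vector of each
training set. Clicked pixels are rarely pure, so up to 100 alternating
refinement rounds follow: each set is unmixed against the current pair of
vectors, the *fitted* contribution of the other stain is subtracted
(floored at 0 componentwise), and the vector is re-averaged and
re-normalized; iteration stops when both vectors move by less than 1e-6.
Subtracting the fitted (rather than the full projected) component is what
makes pure training data a fixed point: for a set that is genuinely one
stain, the non-negative fit assigns zero to the other stain and the
vector does not move. For partially contaminated sets, the pixels with
the least contamination anchor the drift back towards the true direction;
that drift converges slowly, which is why the round cap is generous (the
1e-6 stop ends iteration early whenever the data allow). Models whose
vectors are closer than 5° are rejected as ill-conditioned, and the
condition number of the 3×2 stain matrix is reported.

## Endothelial-area extraction

The DAB abundance map is thresholded at a single global OD value chosen
manually for the whole study (default 0.15, inclusive comparison). The
binary mask is decomposed into connected components (8-connectivity by
default) after hole filling: vessel lumens are unstained, so filling
makes one ring one object — but lumen pixels are never added to $EA$,
which counts mask (endothelium) pixels only. Components below 20 µm² are
discarded as noise. Objects whose second-moment eccentricity exceeds 0.95
are *flagged* as fibroblast-like, never auto-deleted: in the intended
workflow, removal is a human decision recorded in a correction ledger of
ordered add/delete events (adds are polygons, whose shoelace area defines
the manual object's area; deletes reference object labels). $EA$ inside an
ROI is the pixel-union area of all validated objects intersected with the
ROI mask, so $EA \le AA$ always holds.

## Regions of interest

Compartment ROIs are 1-mm-diameter discs in physical slide coordinates
(µm, origin at the canvas top-left). Rasterization uses the half-open
centre-in-disc rule (pixel included iff its centre is strictly within the
radius); $AA$ is the rasterized pixel count times pixel area rather than
the geometric $\pi r^2$, keeping the EA/AA ratio an exact pixel-count
ratio. The rasterized area converges to $\pi r^2$ as pixel size shrinks
and is within 1% at 1 µm/px. A valid patient ROI set has 1–3 ROIs per
compartment; overlaps between ROIs of different compartments produce a
warning, not an error — the T/IF border is genuinely ambiguous and the
conventions do not forbid shared tissue.

## Statistics layer

Per patient and compartment, EA and AA are pooled over ROIs
(\(\mathrm{REA} = 100\,\Sigma EA / \Sigma AA\), not the mean of per-ROI
ratios — so splitting an ROI in two leaves the result unchanged). Group
summaries are unweighted arithmetic means across patients, for the whole
cohort and stratified by nodal status (N0 vs N>N0) or molecular subtype
(Luminal A, Luminal B, Basal-like, HER2; unknown subtypes are excluded
from subtype tables with a logged count). Compartment contrasts are
reported as ratios of group means at full precision; rounding is
presentation-only (2 decimals for REA and ratios, 3 for p-values).

Association between compartments uses the Pearson coefficient with the
exact two-tailed transform $t = r\sqrt{(n-2)/(1-r^2)}$ referred to the
Student-t distribution with $n-2$ degrees of freedom (R's
incomplete-beta-based CDF; the tests check it against direct numerical
integration of the density to 1e-6). Paired compartment differences use
the standard paired t-test with $n-1$ degrees of freedom. $|r| = 1$
returns $p = 0$ with an exact-fit flag; constant inputs are an error
rather than a silent NA.

## The synthetic-slide generator

Phantoms are composed in OD space with the same two-stain model the
pipeline assumes, then degraded the way a real scanner degrades images:

| parameter | default | meaning |
|---|---|---|
| `pixel_size_um` | 0.65 | 10× objective with a 3-MP colour camera |
| `vessel_area_fraction` | 0.02 | wall-pixel fraction, within the 0.5–6% range the REA statistic spans |
| `vessel_radius_range_um` | 8–30 | capillary to small-venule outer radii |
| `wall_thickness_um` | 4 | endothelial ring wall |
| `nuclei_density_per_mm2` | 1500 | counterstain blob density, tumour-tissue order of magnitude |
| `dab_od_peak`, `hema_od_peak` | 0.8, 0.5 | strong chromogen over moderate counterstain |
| `background_rgb` | (235, 235, 235) | acquisition background convention |
| `noise_sd` | 3 | additive camera noise, intensity counts |
| `shading_amplitude` | 0.15 | corner attenuation of the radial cosine vignette |
| `tile_size_px`, `overlap_fraction` | 512, 0.15 | tiling scheme |

Vessels are elliptical annuli (eccentricity up to 0.8) placed by
rejection sampling without mutual overlap until the wall-area fraction is
within 15% of target; if the attempt budget (10× the expected count) runs
out first, generation fails naming the achievable bound rather than
silently under-delivering. The ground truth records the exact wall mask,
the true (jittered) tile offsets, and per-ROI true EA. The white
reference is exactly `background × shading` — so shading correction can be
validated in isolation — and tiles are cut at offsets perturbed by integer
shifts uniform in [−3, +3] px to emulate stage error (the first tile
anchors the frame). Noise is added in intensity space, clipped to
[0, 255] and quantized, matching camera behaviour; all randomness comes
from the single `seed`.

What the phantom does **not** emulate: real chromatin/cytoplasm texture,
staining gradients and edge artefacts, folded tissue, necrosis, lymphatic
vessels, and anisotropic vessel clustering. Passing the recovery tests
therefore shows the pipeline is *numerically* faithful (no systematic
loss between ground truth and measured EA under realistic noise, shading
and tiling), not that the default OD threshold generalizes to any real
staining batch — on real material the threshold remains a supervised,
study-level choice.

## The synthetic-cohort generator

Cohorts are drawn from a correlated lognormal: a trivariate Gaussian
copula with a target correlation matrix applied on the log scale, and
lognormal marginals matched to the requested compartment means and
coefficients of variation (REA is a positive, right-skewed percentage, so
lognormal marginals are the natural choice, and the log scale is where
the copula correlation is parameterized; empirical raw-scale correlations
land close to the same values at these CVs). Defaults reproduce the
reference study population: 50 patients, compartment means
(0.91, 1.95, 4.2)% for (TAS, T, IF), CV 0.5, between-compartment
correlations (0.418, 0.432, 0.655), 13 node-negative patients, and
subtype counts 25/9/5/11. Each compartment receives 1–3 ROIs of
$\pi/4$ mm² each; EA is back-computed from REA and AA so the table is
self-consistent under pooled aggregation.

## Numerical conventions and degenerate inputs

* OD floor at intensity 1 and cap at 3.0; intensities stay float until
  image write time.
* Threshold comparison is inclusive (`>=`).
* Registration never returns an offset outside the search radius; a
  featureless overlap falls back to the nominal offset with a flag.
* Stitch seam ties (equidistant tile centres) keep the earlier tile,
  making assembly order-deterministic.
* `p_from_correlation` returns exactly 1 at $r = 0$ and exactly 0 (with a
  flag) at $|r| = 1$; the paired t-test returns $t = 0, p = 1$ for
  all-zero differences but rejects zero-variance non-zero differences.
* Empty masks, empty cohorts, missing compartments, out-of-bounds ROI
  discs, unknown ledger labels and self-intersecting add-polygons are all
  explicit errors or empty-but-typed results, never silent NAs.

## Problem sizes used in the test and acceptance runs

The shipped tests exercise: five 4-mm² phantoms (2000×2000 px at
1 µm/px) spanning vessel fractions 0.5–6% for end-to-end recovery
(tolerance ±10% relative at default noise, exact at zero noise); a
10,000-pixel comparison of the closed-form unmixer against a two-stage
dense grid search (coarse 0.05 then 1e-3 steps — valid because the
objective is convex); and 5000-patient cohorts for simulator recovery
(means within 3 standard errors, log-scale correlations within ±0.03).
These sizes are the package's own choice of a convincing-but-compact
validation set.

## Known limitations

* Two stains only; a third chromogen is visible in the residual map but
  not modelled.
* Integer-pixel registration; no subpixel refinement, no focus stacking,
  no proprietary WSI container support (PNG/TIFF tile sets only).
* The fibroblast-like flag is a hint for manual review, not a
  classifier; automated morphology-based deletion is deliberately out of
  scope.
* Compartment assignment of ROIs is consumed, not inferred: automatic
  compartment detection is future work.
* Group comparisons are descriptive (means, ratios, pairwise tests);
  no multiplicity correction or outcome modelling is applied.
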