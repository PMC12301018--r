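---
title: "Quantifying biofilm architecture from multi-channel confocal stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying biofilm architecture from multi-channel confocal stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biofilmq)
```

## The problem

Biofilms growing on sewer-pipe concrete drive microbially induced concrete
deterioration: sulfur-cycling communities embedded in an extracellular
polymeric substance (EPS) matrix generate biogenic sulfuric acid at the
concrete surface. Understanding where the EPS components — proteins,
polysaccharides, nucleic acids, lipids — and the bacteria themselves sit
within the biofilm, and how much of each there is, is central to
understanding the deterioration mechanism, particularly how it changes
between low-salinity (freshwater) and high-salinity (coastal) sewage.

The measurement chain this package implements starts from a multi-channel
confocal (CLSM) z-stack of a stained biofilm: each fluorophore channel maps
to one biofilm component (FITC to protein, Calcofluor White to
polysaccharide, Nile Red to lipid, Rhodamine to all bacteria, propidium
iodide to dead bacteria). The analysis follows four steps: shadow
correction, grayscale conversion, image segmentation, and target
measurement. Segmented component volumes feed a pair of ratio estimators
that convert a single measured biofilm mass $m$ (mg) into component masses:

$$\mathrm{EPS}_I = m \frac{V_I}{V}, \qquad
  \mathrm{EPS}_{II} = m \frac{V - V_B}{V},$$

where $V$ is the biofilm volume, $V_I$ the fluorescent volume of component
$I$, and $V_B$ the bacterial volume. Both are dimensionless-volume-ratio
estimators: rescaling all volumes by a common factor leaves the masses
unchanged, so voxel-size calibration errors cancel.

Complementing the imaging, 3D excitation–emission matrices (EEM) of
extracted EPS are scanned on a 200–400 nm excitation / 220–500 nm emission
grid at 5 nm steps; protein-like fluorescence appears as a tryptophan-like
peak (region A, Ex 275–280 / Em 325–350 nm) and a tyrosine-like peak
(region B, Ex 225 / Em 300 nm), whose intensities decline with salinity.

## Pipeline and assumptions

**Axis convention.** All stacks are `(channel, z, y, x)` with voxel size
`(dz, dy, dx)` in micrometers. One canonical layout everywhere prevents
silent transpositions. `depth_origin` records which physical face the first
z-plane is; the default (`substrate_at_z0`) assumes imaging began at the
concrete-adjacent face. Acquisitions oriented the other way set
`free_surface_at_z0` and depth profiles flip accordingly.

**Shadow correction.** The source workflow names the step but not the
algorithm. The default, `flatfield_divide`, divides by a heavily smoothed
copy of the volume and rescales to the input mean. This targets
multiplicative vignetting, the dominant confocal shading artifact. The
background field is estimated with a Gaussian-weighted local *linear*
smoother (Savitzky–Golay order 1) rather than a plain Gaussian mean:
a plain mean flattens linear intensity ramps near the volume faces,
leaving a shading residual precisely where biofilm/substrate interfaces
sit, whereas the local-linear fit reproduces linear gain fields exactly,
edges included. The scale (`scale_um`, default a quarter of the lateral
field) must be much larger than real objects and smaller than the field.
An additive alternative (`rolling_ball_subtract`, a grayscale-opening
background) is provided for halo-type backgrounds.

**Grayscale conversion** is exposed (`to_grayscale`, a validated weighted
channel sum) because the published workflow lists it as a step, but the
quantification path segments each channel separately — collapsing channels
before segmentation would discard exactly the component identity this
analysis is about.

**Segmentation.** Per-channel Otsu thresholding on the full 3D histogram
(256 bins after min–max scaling) is the default; a single threshold per
channel keeps depth bins comparable. Manual per-channel overrides are
first-class and always recorded on the mask (`threshold_used`, `method`),
mirroring practice in commercial 3D software where "the appropriate
threshold was selected" by the operator. A constant channel has no Otsu
threshold; `threshold_segment` raises a degenerate-histogram error, while
the higher-level `assign_components` degrades it to an empty mask with a
message so an all-blank acquisition still yields a complete mask set.

**Component precedence.** The staining scheme mixes the protein,
polysaccharide and nucleic-acid stains and applies the lipid and bacterial
stains singly, so bacteria physically coexist with EPS — bacterial masks
are therefore never competed against EPS masks. Voxels positive in more
than one EPS channel are assigned to the channel with the higher
per-channel z-score (intensity standardized within channel), making each
voxel belong to at most one EPS component. Dead bacteria (PI) are treated
as a subpopulation: their mask is intersected with the all-bacteria mask,
and PI-only voxels are counted and reported.

**Cross-talk checking** works from emission maxima, not full spectra,
because stain tables list point maxima. Each fluorophore's band is the
min–max envelope of its listed emission maxima dilated by a margin
(default 10 nm) on both sides; any intersecting pair is flagged. At the
10 nm margin the five-dye scheme flags Nile Red against both PI and
Rhodamine — a caution to check those channels for bleed-through, which the
synthetic generator can emulate via its `bleed` matrix.

**Total volume $V$.** The published workflow never defines how the biofilm
body was delimited. The default is the union of all component masks —
conservative and reproducible. A `convex_envelope` option (per-z-slice 2D
convex hull of the union, built from voxel corner points so a single voxel
has its full area) approximates a filled biofilm body including unstained
interstitial space; it is never smaller than the union.

**Depth profiles** count mask voxels in depth bins (default 10 μm, the
granularity at which depth enrichment is reported in this field) measured
from the substrate, and normalize within each bin across components — the
stacked-composition reading of a proportion-versus-depth figure. The
alternative normalization (within component across bins) is available via
a flag. K-means layer clustering (`kmeans_layers`) operates on the per-bin
composition vectors; the feature space is a documented choice since the
source only names the method.

**REV analysis** draws seeded random axis-aligned subvolumes (with
replacement) per edge length and reports the coefficient of variation of
the component volume fraction; the REV size is the smallest size with CV
at or below the tolerance (default 0.05). For a spatially homogeneous
random mask the CV follows the binomial closed form
$\sqrt{(1-p)/(p\,n_{\mathrm{vox}})}$, which the test-suite uses as an
oracle.

**Mesh export** extracts the 0.5-occupancy iso-surface by marching
tetrahedra on the Kuhn 6-tetrahedron cube decomposition (consistent across
neighboring cubes, hence watertight). The enclosed volume is computed
exactly for that surface — each tetrahedron contributes 0, 1/8, 1/2, 7/8
or all of its volume depending on how many corners are inside — and
converges to the voxel-count volume as structures grow (within 5% for
digitized spheres of radius ≥ 10 voxels, within ~0.2% at radius 15).

**EEM analysis** clips negative cells on read (with a logged count), masks
first- and second-order Rayleigh scatter bands (default half-width 15 nm)
before detection, and defines peaks as strict 8-neighborhood local maxima
with prominence relative to the global maximum (default 0.1) — relative,
because EEM units are arbitrary, which also makes detection invariant to
uniform intensity scaling. Region B is published as a point (225/300 nm),
so classification uses a ±5 nm window, one grid step, configurable.
Condition comparisons report per-region test/reference intensity ratios;
an absent peak is reported as absent, never as zero.

## The synthetic-data generator

No raw CLSM data are deposited for this system, so the package ships a
seeded generator (`generate_stack`) that builds ground-truthed
multi-channel stacks: random spheres (radius jittered ±30% around
`blob_radius_um`, default 4 μm — the scale of microcolonies and EPS
clusters) are placed with blob-center depths drawn from per-component
depth densities until each component's target voxel count
`round(target_fraction × n_voxels)` is met exactly (the last blob is
trimmed by random subsampling, so realized fractions match targets up to
rounding). Channel intensities are background 20 / foreground 200
(arbitrary units), mixed by an optional bleed matrix, blurred by a
Gaussian PSF proxy, and overlaid with Gaussian noise of
sd = (foreground − background)/snr. Defaults snr = 5 and 1 μm blur
represent a moderately noisy acquisition.

Two presets encode the observed depth regimes: `FQHC` (low salinity)
places all components uniformly over the mid-depth with near-equal
fractions; `SQHC` (high salinity) concentrates bacteria in the surface
layer (Gaussian depth density, mean 15 μm, sd 5 — inside the reported
10–20 μm window), extracellular DNA deep (mean 35 μm, sd 5 — inside
30–40 μm), and weights protein and polysaccharide toward the deep bins.
The protein/polysaccharide depth parameters are illustrative: the source
reports only that they "tend deeper" under high salinity, so those means
(38 and 40 μm, sd 8) are this package's documented choice.

What a green test does establish: the pipeline's arithmetic, its
segmentation contracts, depth-binning, REV statistics and EEM logic are
correct against independent oracles on data whose truth is known exactly.
What it does not establish: fidelity to real biofilm morphology (no
growth model, no depth-dependent attenuation or scattering, no realistic
PSF anisotropy), nor anything about real staining chemistry.

```{r example}
gen <- generate_stack(preset_recipe("SQHC", seed = 7))
masks <- lapply(names(gen$truth$masks), function(cp)
  threshold_segment(get_channel(gen$stack, cp), "manual",
                    manual_t = 110, component = cp))
names(masks) <- names(gen$truth$masks)
quant <- biofilm_quant(masks, m_mg = 25, voxel_size = gen$stack$voxel_size)
quant
prof <- depth_profile(masks, gen$stack$voxel_size, bin_width = 10)
subset(as.data.frame(prof), component == "all_bacteria")
```

## Numerical choices and known limitations

* **Otsu and partial-volume bias.** With a blurred acquisition, the
  boundary shell of intermediate intensities drags the Otsu threshold
  below the edge midpoint: at the default 4 μm blobs with 1-voxel blur and
  snr 5 this inflates masks by roughly +14% (scikit-image's Otsu lands on
  the same threshold — the bias is in the estimator, not the
  implementation). The midpoint threshold between the known background and
  foreground levels is unbiased for symmetric edge profiles and recovers
  volume fractions within ~2.5% under the same conditions; the package's
  recovery tests therefore use manual midpoint thresholds, and real
  analyses should treat Otsu output as a starting point to be checked
  against the recorded threshold. In the noiseless, unblurred limit Otsu
  segmentation is exact.
* Binarization is `intensity >= threshold`; raising a manual threshold can
  therefore never grow a mask (a tested invariant).
* Foreground connectivity is 26-neighborhood; hole filling uses the
  complementary 6-neighborhood for the background, the standard pairing
  that keeps surfaces topologically consistent.
* Depth bins smaller than the z-spacing are rejected rather than silently
  interpolated.
* K-means restarts (default 10) are seeded; inertia is the total
  within-cluster sum of squares and is non-increasing in the restart
  optimum by construction. Ties in the EPS precedence rule break toward
  the first channel in map order (deterministic).
* TIFF support is deliberately narrow: uncompressed grayscale baseline
  TIFF (8/16-bit unsigned, 32/64-bit float), one page per (channel, z)
  plane, with a JSON description carrying voxel geometry. Stacks written
  by this package round-trip bit-for-bit; compressed or proprietary
  microscope formats need prior conversion.
* Mass estimates inherit all segmentation bias: EPS masses are exactly as
  good as the masks and the measured biofilm mass $m$, which is a required
  user input (it cannot be recovered from images).
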