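---
title: "Methods: OCT retinal layer segmentation and morphometry in the developing mouse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: OCT retinal layer segmentation and morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octmorph)
```

## Scope and model

`octmorph` quantifies retinal layer thicknesses in spectral-domain OCT
BM-scan volumes of the developing mouse eye (postnatal days ~7–21). The
raster is a 4-D array `(bscan, repeat, depth, aline)`; depth index 1 is
the most anterior (vitreous) pixel, and all depths are 1-based float
pixels. The physical model underlying every stage is the standard
layered-reflectance picture of the rodent retina: back-scattering is
high where structures lie perpendicular to the beam (nerve fiber layer,
plexiform layers, IS/OS, and — brightest of all — the RPE-Bruch
complex) and low in the nuclear layers. Layer boundaries are therefore
either intensity extrema (RPE band, OPL) or axial-gradient extrema
(vitreous/NFL, NFL/IPL, IPL/INL, IS/OS onset).

## The phantom: what it emulates and what it does not

The synthetic generator (`phantom_config()`, `make_phantom()`) is a
first-class, tested component: it produces the only inputs the package
is validated against, with exact ground truth.

It emulates:

* the acquisition geometry of a BM-scan protocol (default raster
  512 positions × 5 repeats × 512 A-lines, native 3.42 µm/px axial
  pitch in air, tissue index 1.35 → 2.53 µm/px in tissue);
* a curved, laterally smooth retina (polynomial surface in normalized
  en-face radius; default 10 px sag) with layer thicknesses typical of
  the maturing mouse (NFL 15, IPL 55, INL 30, ORL 100, RPE-Bruch
  20 µm, IS/OS occupying the posterior 40 µm of the ORL) and an
  optional radial thickness gradient;
* multiplicative gamma speckle with mean 1 and contrast
  `1/sqrt(shape)` (default shape 4, contrast 0.5). Static tissue keeps
  one frozen speckle field across the repeats — frame averaging does
  *not* remove it, exactly as in real repeated B-scans — while vessel
  voxels redraw their speckle every frame, which is precisely the
  contrast speckle-variance angiography detects;
* depth sensitivity roll-off (`decay^z`, default 0.999/px), an
  additive exponential noise floor, vessel shadowing (0.7× beneath
  vessels), and an ONH modelled as a quasi-cylindrical suppression
  (0.1×) of the RPE-Bruch band within a disk.

It does not emulate: wave-optics propagation, lateral PSF blur and
defocus, polarization, bulk-motion warping beyond rigid shifts, hyaloid
vessels, or pathology. Passing the phantom-recovery suite therefore
demonstrates correctness of the *algorithms* under controlled
speckle/noise, not clinical performance on degenerated retinas — the
detectors assume the canonical reflectance ordering (`RPE_Bruch`
strictly brightest, nuclear layers darker than the IPL), and the
configuration validator enforces it.

Bright thin bands (OPL, RPE-Bruch) are raised-cosine bumps whose peaks
sit exactly on the nominal boundary/band centre, so intensity-peak
detectors have a well-defined sub-pixel truth; sharp layer interfaces
are ideal steps, for which every gradient detector's discrete apex lies
within one pixel of the float truth. That is what makes the "1 px
everywhere, noise-free" identity meaningful rather than vacuous.

## Preprocessing

Stages run in the fixed order dispersion → background → roll-off →
registration → averaging.

* **Dispersion** (`make_fringes()`, `compensate_dispersion()`): fringes
  are modelled under a Gaussian source envelope; compensation multiplies
  by `exp(-i [a2 (k-k0)^2 + a3 (k-k0)^3])` and transforms to depth. The
  coefficients are user inputs (rad/sample² and rad/sample³); matched
  coefficients restore the point-spread FWHM to within 5% of the
  undispersed width, and the tests measure FWHM by interpolated
  half-maximum crossings.
* **Background**: only the depth-profile statistics of the out-of-field
  background volume generalize to the imaging field, so its mean depth
  profile (not voxelwise values) is subtracted, clipped at zero.
* **Roll-off**: a known/user-fitted exponential gain `decay^-(z-1)`;
  no auto-calibration is attempted.
* **Registration** (`register_bscans()`): integer-pixel rigid
  translation per B-scan, each compared to the previously aligned one by
  2-D FFT cross-correlation of repeat-averaged images. Reported shifts
  are the detected displacements; their negation is applied (zero
  fill). Correlation-peak ties break toward the zero shift, so constant
  images are untouched. Sub-pixel refinement is deliberately absent:
  integer recovery is exactly testable and captures the dominant motion.

## Angiography

`speckle_variance()` uses the population variance (divisor N) across
repeats — deterministic and shift-invariant, scaling quadratically with
intensity. `motion_robust_variance()` evaluates every leave-one-out
subset per B-scan and keeps the one with the lowest spatial-mean
variance (ties drop the last frame). The spatial mean of the chosen
subset never exceeds the full-set mean; this follows from the identity
that the average leave-one-out population variance equals
`s² (n-2)/(n-1) ≤ s² (n-1)/n`. Frame removal is per B-scan (a volume
with motion in only some positions keeps its clean frames elsewhere);
this is exposed rather than hidden because the alternative global
reading is plausible. Vessel masks threshold an en-face mean projection
at `mean + 2 SD` and drop 8-connected components below 5 px.

## Segmentation

`segment_retina()` executes: box-kernel denoise → RPE argmax → ONH
detection/exclusion → vitreous/NFL → OPL → IPL/INL → NFL/IPL → IS/OS →
per-surface polynomial artifact correction → ONH masking → ordering
enforcement by clipping (with a warning when any point needed it).

Numerical choices that matter:

* **Denoise**: normalized rectangular kernel, default 3 × 3
  (depth × lateral), reflect padding. Larger axial kernels bias step
  detectors anteriorly; lateral widening smears curved boundaries.
* **Derivative at scale** (`axial_derivative(scale_px)`): the default
  detectors use the dual-window gradient
  `(mean I[z+1..z+w] − mean I[z−w..z−1]) / (w+1)` with `w = 4`, which
  averages speckle on both flanks of an edge while keeping the response
  apex on the interface (for a sharp step it ties on the two flanking
  pixels, like the central difference, and ties resolve anterior).
  `w = 1` is exactly the central difference. Detector gates subtract the
  gradient's reach (`w` plus the kernel blur) from their posterior ends
  so an edge just beyond a gate cannot leak in.
* **Ties**: every argmax/argmin takes the anterior-most depth — a
  deterministic, stated bias of at most one pixel.
* **RPE**: per-A-line intensity argmax; the posterior boundary is the
  band centre plus `rpe_band_halfwidth_px` (default 4 px ≈ half of a
  20 µm band).
* **ONH**: the band `centre ± halfwidth` around the polynomial-smoothed
  RPE surface is projected en face, smoothed 3 × 3, and normalized by
  its median. A strict core threshold (0.45 × median — low enough that
  vessel shadows at ~0.7× cannot register) locates the disruption; its
  width is then measured as the half-level crossing of the radial
  median profile between the interior and the local intact-band level.
  Because the smoothing kernels blur the rim symmetrically, the
  half-level crossing sits on the true edge, and annulus medians are
  insensitive to noisy or shadowed pixels (a threshold-region area, by
  contrast, over-counts rim pixels one-sidedly). Centre and width are
  refined jointly for a few passes; the exclusion mask is the circle of
  the final diameter at the final centroid (quasi-cylindrical: no
  curvature along depth).
* **Priors**: vitreous/NFL is searched `prior_retina_um` (200 µm)
  anterior to the RPE centre within ±50 µm; the OPL weight (squared
  Hann, cos⁴, support 31 px) is centred at half the vitreous→RPE
  distance; the NFL/IPL weight at 15 µm below the vitreous boundary.
  Priors only gate/weight — detections remain data-driven, and the
  noise-free suite shows a 2× wrong NFL prior still recovers the
  boundary.
* **Degenerate rules**: a flat OPL window (relative peak prominence
  < 10%) returns the prior depth flagged low-confidence; an NFL/IPL gate
  with no negative transition stronger than 1% of the volume's largest
  gradient collapses onto the vitreous boundary; an IS/OS detection on
  the posterior gate edge is flagged low-confidence.
* **Artifact correction** (`correct_boundary()`): per B-scan polynomial
  of order 4 (tracks retinal curvature without chasing spikes; "high
  order" is otherwise unspecified). The fit is trimmed: an initial
  least-squares pass ranks the points and the best 75% are refitted, so
  clustered gross deviations — the ONH region reaches ~16% of a central
  B-scan's A-lines at −80 px — can drag neither the curve nor the
  residual scale. Points beyond `2 × scale` from the trimmed curve are
  moved onto it, where the scale is the MAD of the trimmed residuals
  (SD fallback when the MAD degenerates, and an exact-fit tolerance
  when both collapse, e.g. a flat surface with one spike). A plain
  least-squares fit with an SD rule demonstrably fails on the ONH
  case, and naive iterated re-trimming can run away when the first
  curve is dragged — hence the fixed 75% trim. B-scans with fewer than
  `order + 1` valid points inherit the nearest valid B-scan's curve
  and are flagged.
* **Semi-automatic aspects** of the original workflow are represented by
  the prior parameters above; defaults make the pipeline fully automatic
  on phantoms.

## Morphometry

Layer definitions partition the retina so that thickness maps conserve
exactly: NFL = vitreous→NFL/IPL, IPL = NFL/IPL→IPL/INL, INL =
IPL/INL→OPL, ORL = OPL→RPE posterior, total = vitreous→RPE posterior.
The OPL detection (an intensity peak) serves as the INL/ONL boundary;
whether the ORL should instead start at the OPL's posterior edge is
ambiguous anatomy — the partition convention was chosen so the four
layers sum to the total, and it is applied consistently to phantom truth
and measurement, so recovered thicknesses are comparable. The in-tissue
axial scale is `air_pitch / refractive_index` (3.42/1.35 = 2.53 µm/px).
ROI placement is automated and deterministic: the centre maximizing the
Euclidean clearance (EBImage distance transform) from vessels, ONH and
the field edge, ties to the smallest (row, col); manual centres can be
supplied via `roi_spec()`. Annular band ROIs (55 µm wide, adjacent to
the ONH rim and ending at the field-of-view radius) error out when they
would overlap rather than silently measuring a mixed region.

## Statistics

`kruskal_wallis()` delegates the tie-corrected H to
`stats::kruskal.test` with a chi-square reference on k−1 df; an
all-equal sample returns H = 0, p = 1. Quartiles use linear
interpolation of order statistics (`stats::quantile` type 7) throughout,
including the 1.5 × IQR fences (strictly outside; zero-IQR samples flag
nothing; flagged values are reported but retained downstream). One
caveat is stated openly: at n = 10 per group the chi-square reference is
conservative — the attainable level at nominal 0.05 is about
0.038–0.045 — so the level check asserts closeness from below rather
than a symmetric band around 0.05. Pairwise time-point comparisons are
uncorrected two-group tests; model-based multiplicity handling is out of
scope and the thickness table is shaped for external mixed-model
tooling. `bland_altman()` reports bias, normal-theory limits at 90%
two-sided coverage, and the largest absolute difference the interval
admits.

## Problem sizes and verification

The test suite generates all data in code. The recovery study uses five
seeded phantoms at 128 A-lines × 64 B-scans × 5 repeats × 400 depth
pixels under default speckle — large enough that every boundary's MAE
and each layer's ROI-mean error are stable (observed margins: MAE
≤ 0.83 px against a 1 px bound; thickness error ≤ 1.1 µm against a
2.53 µm bound; vessel Dice ≈ 0.85; ONH diameter within 0.8 px of the
configured 20 px). Full-protocol 512 × 512 rasters are reachable through
the same configuration object. `scripts/acceptance.R` recomputes the
same quantities from scratch against the installed package.

## Known limitations

Boundary detection assumes the canonical reflectance ordering and an
RPE-Bruch band that is distinctly the brightest structure; retinas
violating it (degeneration, severe shadowing) are out of scope.
Registration is integer-pixel and rigid. The angiography module detects
vessels but makes no attempt at flow quantification or deep-plexus
density. TIFF volume storage quantizes to 32 bits behind a power-of-two
normalization (sidecar-recorded); use `.rds` where bit-exactness
matters.
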