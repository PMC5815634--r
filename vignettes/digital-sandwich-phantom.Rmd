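---
title: "A digital twin of the subresolution sandwich phantom for dopamine-transporter SPECT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A digital twin of the subresolution sandwich phantom for dopamine-transporter SPECT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssptwin)
```

## The method and its assumptions

Subresolution sandwich phantoms (SSPs) replace the fixed fillable
cavities of conventional striatal phantoms with a stack of paper sheets
printed by an inkjet whose black cartridge is loaded with a mixture of
radioactive solution and ink. Sheets are interleaved between thin
attenuating slabs; as long as the sheet pitch stays below half the
camera's extrinsic resolution, the discrete layers are invisible in the
image and the stack behaves like a continuous activity distribution.
The attraction for ¹²³I-FP-CIT (dopamine transporter) imaging is
flexibility: any striatal shape or uptake pattern can be printed,
whereas a cavity phantom is frozen at one idealised anatomy that is
known to reconstruct with a medial–laterally elongated striatal
footprint unlike real patients.

`ssptwin` implements the complete digital counterpart of that
workflow, from printer calibration to quantified reconstruction:

1. **Ink model.** The printer's response is a monotone map from input
   greyscale `g ∈ [0, 1]` (0 = white, 1 = black) to printed activity
   per unit area. Replicate counter measurements at discrete levels are
   averaged, passed through isotonic regression (`stats::isoreg`) and
   interpolated piecewise-linearly; the curve is anchored at
   `A(0) = 0`, so inputs must be background-subtracted. Levels above
   the saturation threshold whose replicate coefficient of variation
   exceeds 0.10 are flagged and excluded — heavily inked paper
   saturates and responds erratically, which is why the design never
   prints above `g = 0.9`. Solving the two-level design means finding
   `g_brain` with `A(0.9)/A(g_brain)` equal to the target
   striatum:brain count-density ratio (8:1 for a normal subject);
   `invert_for_ratio()` does this by bisection on the monotone curve to
   a relative tolerance of 1e-9, far below one 8-bit greyscale step.
2. **Template and assembly.** The label volume (brain, left/right
   putamen and caudate) is sliced into 2 mm transaxial sheets by
   nearest-neighbour sampling at each sheet's z-centre — interpolation
   would manufacture intermediate greyscales with no calibration
   meaning, so the two-level design is preserved exactly. Sheets are
   deposited into the nearest 1.9 mm attenuation slab (maximum
   sheet-to-slab misregistration 0.95 mm, reported in the phantom
   metadata), and head compartments become attenuation values
   0.168 cm⁻¹ (printed soft tissue) and 0.225 cm⁻¹ (bronze-doped bone
   shell), the measured values of the printed head at 140 keV.
3. **Acquisition.** A parallel-beam projector (low-energy
   high-resolution collimator) rotates the volume into the detector
   frame with a mass-preserving bilinear splat, applies Beer–Lambert
   attenuation along each ray, blurs each depth plane with a Gaussian
   of `FWHM(d) = sqrt(3.8² + (0.044 d)²)` mm, and bins the result. The
   defaults emulate a clinical protocol: 60 views over 180° per head,
   two opposed heads merged into 120 views over 360°, 14 cm radius of
   rotation, 3.68 mm bins. Exposure per view is the smallest integer
   number of seconds whose expected total reaches 1.5 × 10⁶ counts,
   then counts are drawn Poisson per bin under a recorded seed.
4. **Reconstruction.** OSEM with the standard multiplicative update,
   angularly interleaved subsets and a uniform positive start; the
   clinical settings are 2 iterations × 10 subsets followed by a 3-D
   Butterworth post-filter `H(f) = 1/sqrt(1 + (f/0.7)^{20})` on radial
   frequency in cycles/cm. The default reconstruction projector models
   neither attenuation nor the PSF, as in routine clinical
   processing; matched-model flags exist for convergence studies.
5. **Quantification.** Striatal binding ratios use the specific-uptake
   ratio `(mean_VOI − mean_ref)/mean_ref` with VOIs taken from the
   ground-truth labels and the reference region equal to brain minus
   the striata dilated by 10 mm. Striatal shape is measured on a slab
   summing the 10 central brain slices: per side, pixels above half the
   reference-subtracted side maximum form the footprint, the
   anterior–posterior extent is its bounding extent, and the
   medial–lateral extent runs from the brain midline to the lateral
   edge. Their ratio (AP/ML) separates realistic striata (> 1) from
   the fixed-cavity reference shape (≈ 1.0).

## Worked example

```{r pipeline, eval = FALSE}
res <- run_ssp_study(seed = 1)
res$exposure_s        # solved seconds per view (about 30)
sum(res$counts$data)  # total detected counts (>= 1.5e6)
res$report            # SBRs, AP/ML extents and aspect ratios
```

On the default crescent-striata head this prints striatal binding
ratios near 2.4–2.8 and AP/ML aspect ratios near 1.7 on both sides.
The SBRs sit well below the design contrast of 7: with ~10 ml striata,
a 10 mm-class system resolution and no resolution modelling in the
reconstruction, partial-volume losses are severe — exactly the bias
direction seen in clinical semi-quantification. The matched-model test
in the suite confirms the machinery: with noiseless, blur-free,
matched projector/reconstruction, recovered SBRs return to within 5%
of 7.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| Saturation threshold | 0.9 greyscale | highest stable printed level; 0.95 and 1.0 show inflated replicate spread |
| Design ratio | 8 | striatum:brain count-density ratio of a normal subject |
| Sheet pitch | 2 mm | template slice thickness; below half a typical 8–10 mm extrinsic FWHM |
| Slab thickness | 1.9 mm | printed attenuation slab |
| μ soft / bone | 0.168 / 0.225 cm⁻¹ | measured printed materials at 140 keV |
| Views / arc / heads | 60 / 180° / 2 | clinical orbit, merged to 120 views over 360° |
| Radius of rotation | 14 cm | clinical orbit radius |
| Bin / voxel size | 3.68 mm | reconstructed pixel size (zoom 1.2) |
| PSF | 3.8 mm intrinsic, 0.044 slope | representative LEHR response (~10 mm FWHM at 14 cm) |
| Count target | 1.5 × 10⁶ | clinical total-count floor |
| OSEM | 2 it × 10 subsets | clinical protocol |
| Butterworth | cutoff 0.7 cycles/cm, power 10 | clinical post-filter |
| Reference margin | 10 mm dilation | limits striatal spill-in to the reference VOI |
| Sensitivity | 18 cps/MBq | folds collimator efficiency and energy window into one constant; places solved exposures at the clinical ~30 s/view regime |
| Phantom activity | 70 MBq | ≈4 ml of 18.5 MBq/ml ink solution allowing for ~45 min assembly decay of ¹²³I |

## What the synthetic fixtures emulate — and what they do not

`make_stylized_head()` builds an ellipsoidal brain (semi-axes
70 × 85 × 65 mm) inside a soft-tissue head with a 6 mm bone shell
(outer semi-axes 80 × 95 × 75 mm). Striata are either curved
anterior–posterior elongated crescents (~10 ml per side, AP/ML
bounding ratio ≥ 1.3, emulating normal anatomy) or medial–lateral
elongated bars (the fixed-cavity geometry). `make_synthetic_curve()`
emulates the calibration experiment with a saturating response
`A(g) = 100 (1 − e^{−3g})` — concave and monotone like a real ink
profile, with ~95% of full scale reached by `g = 1` — 12 levels, 5
replicates, 5% multiplicative replicate noise, and six-fold inflated
noise at the 0.95 and 1.0 levels to emulate paper saturation.

The fixtures deliberately omit cortical folding, CSF spaces and
ventricles, serotonergic uptake in pons/thalamus, scatter and
high-energy septal penetration of ¹²³I, and registration error in VOI
placement (VOIs come from ground truth, so registration-induced bias
in clinical semi-quantification software is *not* reproduced). Passing
tests therefore validate the printing/assembly/acquisition arithmetic
and the statistics on a clean geometry; they do not certify absolute
SBR accuracy on patient-like data.

## Numerical choices

* **Rotation operators.** The forward projector rotates with a
  bilinear *scatter* (each source voxel distributes its activity to
  the four surrounding target pixels), which conserves total activity
  exactly for content inside the field of view, making the projected
  total independent of view angle to machine precision. The
  backprojector uses the exact adjoint (bilinear gather with the same
  weights) — adjointness holds to machine precision, which OSEM's
  convergence theory assumes.
* **Attenuation integral.** The ray integral uses half the emitting
  voxel's own μ plus the full μ of voxels between it and the detector
  (midpoint convention), in cm.
* **Exposure floor and ties.** The exposure solver never returns less
  than 1 s; a zero total expected rate is an error, not a zero.
* **Degenerate inputs.** All-zero projections reconstruct to an
  all-zero volume with a warning (the multiplicative update's
  absorbing state); empty brain masks refuse template building; a
  phantom extending beyond the orbit's field of view is refused rather
  than silently truncated.
* **Sheet binning ties.** A sheet exactly between two slabs goes to
  `which.min` order (the lower slab); with 2 mm sheets on 1.9 mm slabs
  no two sheets share a slab because the sheet pitch exceeds the slab
  pitch.
* **Thresholding.** Template segmentation in the planar check is the
  printed footprint; image segmentation thresholds at half the brain
  plateau (median over the footprint), which for a blurred step edge
  crosses at the true boundary.

## Design choices where the field leaves options open

* **Butterworth convention.** Vendors disagree on the meaning of
  "power"; here it is the exponent `n` in `1/sqrt(1 + (f/fc)^{2n})`,
  documented and configurable.
* **Subset ordering.** Angular interleave (view `i` → subset
  `i mod 10`), the standard balanced choice.
* **Registration surrogate.** The nonlinear atlas-to-CT registration
  of the physical workflow is replaced by a user-supplied affine
  transform: the phantom mathematics needs only a geometric mapping
  contract, and nonlinear registration is external tooling. Pixels
  mapped outside the soft-tissue compartment are cleared and counted.
* **ML extent convention.** Whether manual calipers measure each
  striatum from the midline or across its own width is ambiguous;
  the default measures from the brain midline to the lateral edge,
  with a bounding-box alternative (`ml_mode = "bbox"`).
* **View merging.** "60 projections over 180° per detector" with
  opposed heads is taken as 120 distinct views over 360°; the
  alternative reading (60 total) is one argument away in
  `acquisition_geometry()`.

## Problem sizes

The default study runs at the fixture's native resolution: an
84 × 100 × 80 label grid at 2 mm, a 64-bin matrix at 3.68 mm with 120
views, and OSEM at 2 × 10. One full design→assemble→simulate→
reconstruct→quantify pass takes roughly 10–15 s on one CPU; the
matched-model convergence tests use 32³-class grids with up to 20
iterations.

## Known limitations

Scatter, septal penetration and energy response are not modelled, so
absolute count rates rest on a single folded sensitivity constant.
The clinical (unmatched) reconstruction leaves strong partial-volume
bias in SBRs, as intended. Dice values from the planar check are
slightly optimistic relative to a physical printer because ink
deposition noise and paper warping are not simulated. Aspect-ratio
statistics inherit a half-pixel quantisation from footprint
thresholding at 3.68 mm pixels.
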