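---
title: "HU-to-BMD calibration with and without a phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HU-to-BMD calibration with and without a phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(densicalib)
```

## The problem

Quantitative CT turns Hounsfield units (HU) into calcium-hydroxyapatite
(CaHA) equivalent bone mineral density (BMD, mg/cm³) through an affine
map. Where that map comes from matters: it differs between scanners,
drifts with reconstruction kernels, and — for patient-specific
biomechanics such as femoral strength models — its errors propagate
nonlinearly into the endpoint. This package implements and compares three
ways of obtaining the map for a femoral CT scan:

1. **Phantom calibration**: the patient lies on a solid phantom with four
   CaHA rods (0, 50, 100, 200 mg/cm³). Mean HU per rod, pooled over nine
   diaphyseal slices, is regressed against the nominal concentrations.
   This is the gold standard; it travels with the patient and sees the
   same scan-specific artifacts the bone does.
2. **Air–fat–muscle (AFM) calibration**: phantomless and fully automated.
   The scan's own air, subcutaneous fat and muscle act as a three-point
   internal phantom.
3. **Non-patient-specific (NPS) calibration**: one fixed cohort-average
   function, `BMD = 0.82·HU − 4.2`, for every scan.

## The AFM procedure and its assumptions

On the nine selected diaphyseal slices the pipeline:

1. thresholds at −500 HU (midway between air and fat, so any body tissue
   passes), labels in-plane connected components of the projected mask,
   drops components below 100 mm² (speckle, cables), and picks the
   component on the patient-right side under the volume's display
   convention;
2. takes the component's bounding box expanded by `ceiling(10 mm /
   pixel_spacing)` pixels per in-plane side, so surrounding air enters
   the region of interest;
3. builds one combined histogram of all ROI voxels at 1-HU bins — no
   smoothing, since the tissue peaks are massive relative to bin noise;
4. finds the tallest bin inside each tissue's search window (air
   [−1024, −900], fat [−300, −30], muscle [0, 100] HU), then refines it
   to the mode within ±50 HU. With raw 1-HU bins the refinement is the
   windowed argmax again; it earns its keep when the first pass ran on
   smoothed or coarser-binned data, or when the initial peak is a spike
   (e.g. the −1024 export floor) flanked by a taller in-window bin.
   Modes, unlike means, ignore outliers entirely as long as the outliers
   stay outside the ±50 window;
5. fits least squares of peak HU on the reference densities
   (−840, −80, 30 mg/cm³ for air, fat, muscle) and reports
   `HU = slope·BMD + intercept` with its R².

The fit direction deserves a word: AFM is conventionally reported as
HU-on-BMD (slope ≈ 1.2) while phantom and NPS maps are BMD-on-HU
(slope ≈ 0.8). `calibration_function` carries the direction explicitly
and `bmd_from_hu()` inverts as needed — the two conventions differ by a
reciprocal, and leaving the direction implicit is a classic source of
silent sign/scale bugs.

Key assumptions: the leg contains representative subcutaneous fat and
muscle (pathologies that shift soft-tissue attenuation violate this); the
scanner change is approximately affine in HU (then the method
self-corrects exactly, which is what the kernel-perturbation tests
exercise); the reference densities transfer across patients (they were
derived by phantom-calibrating tissue peaks in a reference subgroup,
averaging, and rounding to the nearest 10 — `derive_reference_densities()`
reproduces that procedure for new cohorts, rounding halves away from
zero).

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| reference densities (air, fat, muscle) | −840, −80, 30 | mg/cm³ | cohort-derived constants shipped with the method |
| tissue search windows | [−1024,−900], [−300,−30], [0,100] | HU | separate the three histogram peaks; config-exposed because an uncorrected protocol shift moves them |
| mode half-width | 50 | HU | outlier-robustness window of the mode refinement |
| ROI margin | 10 | mm | ~1 cm of air on each side of the leg |
| body threshold | −500 | HU | midway between air (≈−1000) and fat (≈−90) |
| min component area | 100 | mm² | ignores speckle; any limb is far larger |
| rod densities | 0, 50, 100, 200 | mg/cm³ CaHA | the four-rod solid phantom |
| slices | 9 | – | diaphyseal protocol; slice choice is a user parameter since the anatomical start-slice rule is not automatable on synthetic data |
| surrogate threshold, γ | 150, 2 | mg/cm³, – | bone mask and nonlinearity of the strength surrogate |

Cross-calibration presets (`hu_correction_preset()`): Philips-2
`0.998·HU + 5.48`, Toshiba `0.98·HU − 3.32`, Toshiba detail kernel
`0.97·HU + 27.54`; the reference scanner and GE are identities. These are
measured constants, applied before *phantom* fitting only — AFM and NPS
deliberately receive no correction, which is exactly the contrast the
comparison module probes.

## The synthetic generator

`make_scan()` renders a leg cross-section — concentric marrow (0 mg/cm³),
cortical shell (1000), muscle (30) and fat (−80) cylinders in air (−840)
— resting above a slab bearing the four rods, on a 192×192 grid at
0.9375 mm pixels, nine 3-mm slices. Densities are specified in
CaHA-equivalent mg/cm³ so the ground-truth scanner mapping
`HU = gain·ρ + offset` is exactly affine and its inverse is the true
calibration; the default mapping (1.194, 2.232) places air near −1001 HU,
fat near −93 and muscle near 38, where a protocolised scanner puts them.
The cortex value is a rendering default only — never a calibration
reference, consistent with pilot evidence that adding cortical tissue
does not improve internal calibration (cortical density varies too much
between patients).

Gaussian noise (default SD 10 HU, typical soft-tissue noise for a 3-mm
abdominal reconstruction) is added, then voxels are rounded to integer HU
and clamped to the 12-bit export range [−1024, 4000]. Both choices are
deliberate realism with visible consequences:

* **Integer rounding bounds recovery accuracy.** A peak or rod mean can
  be off by up to 0.5 HU, so noiseless parameter recovery is accurate to
  ≲1 mg/cm³ *within each method's reference span*, but extrapolation
  amplifies the quantisation error — at HU ≈ 1600 a phantom fit whose
  rods span only 0–240 HU can be several mg/cm³ off for unlucky affine
  mappings. The property tests therefore assert ≤1 mg/cm³ recovery over
  the full diagnostic range for the default study mapping, and within the
  reference span for arbitrary mappings. This mirrors a real limitation
  of both methods: all their references sit at trabecular densities and
  below, and cortical BMD is an extrapolation.
* **The −1024 floor creates a spike.** At noise SD 20 about 12% of air
  voxels clamp to −1024, and the raw air-window argmax lands on the floor
  spike rather than the true ≈−1001 peak (an error of ~23 HU at air,
  ≲1 mg/cm³ at bone densities after the fit). At the default SD 10 the
  spike holds ~1% and the true peak wins.

`perturb_kernel()` emulates an aberrant reconstruction kernel by applying
the inverse of a known forward correction plus optional in-plane Gaussian
blur; the perturbed export is *not* re-clamped, standing for the aberrant
scanner's own (affinely related) export. What the generator does **not**
emulate: beam hardening, phantom shadow artifacts from air gaps, metal
and motion artifacts, lesions, and anatomical variation along the slice
axis. Passing tests therefore demonstrate correctness of the estimation
machinery under affine scanner physics with additive noise — not
robustness to structured clinical artifacts.

## Numerical and design choices

* Histogram peak/mode ties break toward lower HU — an arbitrary but fixed
  rule that keeps the pipeline deterministic.
* Rod voxel selection pools voxels across the nine slices before
  averaging; with equal per-slice counts this equals averaging per-slice
  means. Rod localisation comes from a geometry sidecar/config, not image
  detection.
* The NPS function averages per-scan calibration *parameters* (slopes and
  intercepts), not a refit of pooled data.
* Corrected HU are kept real-valued after `apply_hu_correction()`; the
  export quantisation happened once, at acquisition, and re-rounding
  would only add error.
* The phantom fit regresses BMD on HU (`bmd_on_hu`); the printed NPS form
  implies that convention, and it is the direction in which the map is
  consumed.
* The strength surrogate (`Σ BMD^γ · voxel volume` above 150 mg/cm³,
  γ = 2) is a deliberately simple nonlinear endpoint for propagating
  calibration differences; it is labelled in arbitrary units everywhere
  and is not a failure load. Finite-element strength modelling is out of
  scope; the per-scan results table is exported so any downstream model
  or mixed-effects analysis can consume it.
* Bland–Altman limits of agreement use the fixed 1.96 normal-theory
  multiplier; differences are reported method-minus-phantom.
* CLI artifacts embed seed, package version and a config hash;
  timestamps are omitted from structured outputs so byte-identical reruns
  are checkable.

## Problem sizes in the tests

The shipped test-suite and acceptance runs use the default 192×192×9 grid
(~330k voxels per scan), cohorts of 1–4 scans, and 20 seeded scans for
the AFM fit-quality summary — small enough to run in seconds while
leaving every estimator's sampling error well inside the asserted
tolerances (a rod mean at noise SD 20 pools 1161 voxels, SE ≈ 0.6 HU).

## Known limitations

* The leg-ROI "square region" is implemented as the margin rule (tight
  bounding box + 1 cm of air per side), which yields a rectangle for
  non-circular legs.
* Reference densities and search windows assume non-contrast,
  non-pathological soft tissue.
* DICOM support covers uncompressed single-frame little-endian series
  with 16-bit pixels — the common CT export — not compressed transfer
  syntaxes or multiframe objects.
* With heavy noise the air peak merges with the −1024 export floor; the
  mode refinement mitigates but cannot beat a floor spike taller than the
  true peak.
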