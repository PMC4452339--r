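---
title: "Dot-filter and centerline distance rules for vessel-attached nodules: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dot-filter and centerline distance rules for vessel-attached nodules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dotcenter)
```

## The model and its assumptions

A pulmonary nodule in a 2D CT slice is modelled as a rotationally symmetric
Gaussian blob `d(x, y) = A·exp(-((x-cx)² + (y-cy)²)/2σ²)`, a vessel as a
line with the same Gaussian cross-profile. A nodule of radius `r` maps to
`σ = r/3`, so the clinically interesting diameter range 3–30 mm maps to
σ ∈ [0.5, 5] mm. These models justify the two pillars of the method:

1. **Blob enhancement.** The Hessian eigenvalues (ordered `|λ1| ≥ |λ2|`)
   of the dot model at its center are `λ1 = λ2 = -A/σ²`; for the line
   model the along-line eigenvalue vanishes. The measure
   `w_d = λ2²/|λ1|` (for `λ1, λ2 < 0`, else 0) is maximal on blobs,
   exactly zero on ideal line interiors, and — because it is quadratic in
   the weak eigenvalue — strongly suppresses elongated structure.
2. **Centerline geometry.** A genuine attached nodule carries its mass
   *off* the vessel axis; the blob-like false positives at vessel ends and
   crossings sit *on* it. Distances from the suspect centroid to the local
   centerline (d1, to the fitted line; d2, to the nearest skeleton pixel)
   against a 1.5 mm threshold give the three-way rule described in the
   README.

Assumptions worth keeping in mind: bright structures on a darker
background (soft tissue vs. lung parenchyma after gray thresholding);
approximately isotropic pixels with known spacing; nodules compact enough
that one response blob represents them; vessels thin relative to nodules.
Low-contrast nodules and pleura-attached nodules are out of scope.

## Parameters

| parameter | default | units | why |
|---|---|---|---|
| gray threshold | 130 | 8-bit intensity | separates soft tissue from parenchyma; histogram-derived in the source material, kept configurable since the histogram is not reproducible here |
| pre-smoothing σ | 1 | px | noise suppression before differentiation |
| r0, r1 | 1.5, 15 | mm | nodule radius range (diameters 3–30 mm) |
| N (scales) | 5 | — | geometric ladder resolution across [r0/3, r1/3] |
| scale normalization | on | — | raw `w_d` of a dot scales as 1/σ²; multiplying by σ_px² makes responses comparable across scales so the max picks the right one |
| suspect threshold | 0.1 | fraction of max response | binarization level for suspect regions |
| min area | 4 | px | speckle rejection |
| prune iterations | 8 | — | burr extinguishing passes on the skeleton |
| d threshold | 1.5 | mm | decision boundary for d1/d2 |
| pixel spacing | 0.6 | mm/px | thin-section CT in-plane spacing |

The number of scales and the σ schedule use the geometric form
`σ_k = ρᵏ·(r0/3)`, `ρ = (r1/r0)^(1/(N-1))`, `k = 0..N-1`. The source
formulation indexes the ladder ambiguously (an exponent of N with a ratio
defined over N-1 steps); we resolve it so that the first and last scales
land exactly on r0/3 and r1/3, which is the only reading in which the
ladder spans the stated radius range.

`w_d` is stated in the literature as `λ2²/λ1` with `λ1 < 0`, which is
literally negative; we implement the magnitude `λ2²/|λ1|` so that
"select the maximum over scales" is meaningful. Eigenvalue ties
`|λ1| = |λ2|` assign the more negative value to λ1.

## What the phantoms emulate — and what they do not

The phantom module generates every test input: single Gaussian dots and
lines, the five-dot (σ = 2, 4, 6, 8, 10 px) / three-line demonstration
panel, single/Y/X vessel models, and attached-nodule scenes with ground
truth (nodule center, σ, vessel axis, perpendicular offset).

Design choices that deserve justification:

* **Compositing.** Non-overlapping demonstration scenes composite by
  addition (linear superposition of the Gaussian models). Adhesion scenes
  (vessel models, attached-nodule phantoms) composite by per-pixel
  **maximum**: two soft-tissue structures that touch form a union of
  tissue, not a doubling of density. Additive compositing of two
  near-saturation structures clips into a plateau whose blob center lies
  *between* nodule and vessel — the phantom would then contradict its own
  declared ground-truth center, and parameter recovery would measure the
  artifact, not the method.
* **Line ends.** `render_line` caps its ends by default — vessel ends must
  exist, because end-of-vessel blob responses are exactly the false
  positives the classifier is for. The demonstration panel is the one
  exception: its purpose is to show line *suppression*, and the underlying
  line model has no termination term, so panel lines taper their amplitude
  smoothly to zero (smoothstep over 30 px). With hard caps the panel would
  grow end-blob suspects at ≈16 % of the maximum response, above the 0.1
  suspect threshold — structures that belong to the vessel-model scenes,
  not to the panel.
* **Attached-nodule geometry.** The nodule hangs off the vessel end like a
  ball on a stick: by default its center is placed along the axis beyond
  the tip as far as the adhesion constraint allows (capped at one nodule
  σ), at the requested perpendicular offset. A Gaussian of amplitude 255
  crosses the 130 threshold at radius 1.16 σ, which gives the contact
  distance used by that constraint.
* **Stated world of the recovery suite.** 200 phantoms with perpendicular
  offsets uniform in [0.75, 4.5] mm (0.5–3 × the 1.5 mm threshold),
  orientation uniform in [0°, 180°), nodule σ uniform in [4, 7] px
  (≈ 9–17 mm nodules — mid-size juxtavascular lesions) and vessel σ in
  [1.5, 2.5] px (≈ 2–3 mm segmental vessels). Offsets within ±20 % of the
  threshold are excluded from scoring.

What the phantoms do **not** emulate: CT noise texture and HU calibration,
lung anatomy and parenchymal background, partial-volume and
reconstruction-kernel effects, non-straight vessels, and nodules attached
to the pleural wall. A green test therefore establishes the correctness of
the *algorithmic chain* — enhancement, centerline extraction, distance
rules — on scenes that satisfy the model assumptions; it does not
establish clinical sensitivity or false-positive rates.

## Numerical choices

* **Derivatives.** Gaussian-derivative kernels truncated at 4σ, reflective
  boundaries; second-derivative kernels are shifted to zero sum so constant
  images produce exactly zero response. Eigenvalues come from the closed
  form for symmetric 2×2 matrices.
* **Thinning guard.** The two-subiteration deletion rules, applied
  simultaneously, can extinguish a small compact component in one pass (a
  2×2 remnant satisfies every condition at once). Because a centerline
  transform must not destroy connectivity, one pixel (smallest linear
  index, deterministic) of any component that would vanish is spared.
  Component labels are computed once — thinning only removes pixels.
* **Staircases.** On near-diagonal lines this thinning family leaves
  two-pixel staircase steps whose pixels have three *mutually adjacent*
  neighbors. Branch points are therefore defined by the crossing number
  (cyclic 0→1 transition count ≥ 3), not by the raw neighbor count, both
  in `skeleton_points()` and in the spur-pruning walk.
* **Spur pruning.** An endpoint is deleted only when walking its branch
  reaches a junction within the protected length (5 × iterations);
  endpoints of pure paths and of long limbs are protected, so unbranched
  vessels keep their length. A final re-thinning pass removes the corner
  stubs endpoint deletion can leave at junctions.
* **Suspect splitting and centroids.** One thresholded response region can
  hold several blobs (a nodule and the adjacent vessel end merge at the
  0.1 level). Regions are split at significant local maxima (≥ 0.5 × the
  region peak), with two safeguards: maxima within 3 px are one peak, and
  a lower maximum that stays connected to a higher one above 80 % of its
  own height is a shoulder of the same blob (the max-over-scales field
  stitches scales and produces such bumps), not a separate structure.
  Centroids are response-weighted over each suspect's half-peak core, so
  low-response skirts cannot drag the center of mass.
* **Gap filling and debris.** Removing suspect footprints can sever a
  crossing; components that continue beyond the bridging range (twice the
  removed region's equivalent diameter) are re-bridged to the region
  centroid with 1-px lines, which restores a centerline *through* the
  crossing. Components confined to the removed blob's neighborhood are
  fragments of the eliminated suspect (its sub-threshold rim) and are
  deleted — leaving them in place would re-create a skeleton inside the
  suspect and destroy the d2 signal that identifies vessel ends.
* **Ties and boundaries.** The gray-threshold comparison is ≥ (boundary to
  foreground). Distance equality d = t is assigned to the vessel classes —
  fewer nodule calls on the boundary. The local line fit is total least
  squares (principal axis) over the 15 skeleton pixels nearest the
  centroid; vertical lines are representable (β = 0) and reported as
  undefined slope.

## Known limitations

* The d1 rule measures the *detected blob's* offset. A small nodule deeply
  merged with a comparably sized vessel tip yields a composite lump whose
  center genuinely lies between the two structures; no centroid estimator
  can recover the planted offset in that regime. This is the main residual
  failure mode of the recovery suite (and the analogue of the method's
  reported misses on very small nodules).
* DICOM and TIFF I/O are not provided (no reader available in the
  supported dependency set); PNG (8-bit write, 16-bit read) and ASCII PGM
  cover the tool's needs. Spacing must be supplied for formats that do not
  carry it.
* 2D only, by design: the method operates slice-wise.
* The skeleton of a curved vessel is fitted locally by a straight line;
  strongly curved vessels near a suspect bias d1. The 15-pixel window
  keeps this bias small for realistic curvatures but it is not zero.
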