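---
title: "Neurite morphometry: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neurite morphometry: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuritegeom)
library(dplyr)
```

## The problem

Sub-micrometre X-ray tomography of Golgi-stained cerebral cortex resolves
individual neurites — dendrites and axons — as bright tubes in a cylindrical
field of view some 64–122 µm across. Once traced into Cartesian coordinate
models (node trees carrying a 3D position and a local radius per node, all
in micrometres), a neurite becomes a 3D curve, and its shape can be
summarised by two Frenet invariants: **curvature** κ, the reciprocal of the
radius of the osculating circle (µm⁻¹), and **torsion** τ, the signed rate
at which the curve leaves its osculating plane (µm⁻¹; the sign encodes
handedness). Case–control comparisons of these invariants — schizophrenia
versus matched control cortex — are the analysis this package implements end
to end, together with spine morphometry (length, neck and head radii) and a
synthetic generator that stands in for the original image volumes.

## The data model

A `tissue_model` holds every traced constituent of one dataset as a tibble
of nodes (constituent id, type, node id, parent id, x, y, z, r). Types are
`soma`, `spiny_dendrite`, `smooth_neurite`, `blood_vessel`, `spine`,
`unclassified`. Spines always carry an attachment record (which constituent
and node they sit on); neurites may attach to a soma the same way. Two file
formats are supported: standard 7-column SWC (type codes 1–3 plus custom
codes 7 = vessel, 8 = spine, chosen because SWC reserves no codes for
either) and a lossless tab-separated native format with a metadata header
and an attachment sidecar.

Neurite trees are split into **segments** at every ramification point:
maximal chains whose interior nodes have exactly two neighbours. Branch
nodes are duplicated into each incident segment so every segment has a
geometric endpoint; without duplication, curvature next to a branch point
would be undefined. Segments whose constituent is not connected (through
the attachment graph) to any soma-bearing constituent are flagged
**orphans** — distal arbor fragments whose soma lies outside the field of
view. Orphans are analysed separately because they represent distal
neurites, where the case–control contrast is strongest.

## Discrete estimators

The estimators operate on chains resampled to uniform arc-length spacing
(linear interpolation, endpoints preserved; default 0.5 µm, matched to the
synthetic generator's step and validated on helix oracles). Resampling
should only ever coarsen a chain: resampling below the original node
spacing places nodes on chords of the polyline rather than on the curve.

* **Curvature** at each interior node is the Menger curvature of the node
  and its two neighbours, `4A / (|ab||bc||ca|)` — exactly `1/R` for any
  three points on a circle of radius `R`, and convergent to the Frenet
  curvature as spacing shrinks.
* **Torsion** on each 4-node window comes from the signed tetrahedron
  volume: for spacing `h`, `det(p2−p1, p3−p1, p4−p1) ≈ κ² τ h⁶`, so
  `τ = 6V / (κ² h⁶)` with κ the window's mean Menger curvature. The sign is
  the window's handedness; a right-handed helix is positive (a convention
  this package fixes, since the underlying analysis only requires
  symmetry about zero). Windows with κ below `1e-6` µm⁻¹ are degenerate
  (torsion of a straight run is undefined) and are excluded, which is why a
  segment's torsion n is at most its curvature n.

On the circular helix `(r cos t, r sin t, c t)` — the analytic oracle, with
κ = r/(r²+c²), τ = c/(r²+c²) — the estimators at 0.2 µm spacing recover
both to well under 1% and 2% respectively; mirroring negates every torsion
value exactly and leaves curvature untouched.

Per-segment means are unweighted node averages, per-case means unweighted
segment averages, and group summaries unweighted case averages. Unweighted
case averaging is what makes the published orphan-curvature contrast come
out at a 51% increase (segment-count weighting would give ~50%), and it
matches the four-versus-four framing of the Welch test.

Spine **length** is measured along the chain from base to tip (a curve
parameter, like curvature and torsion), not as the Euclidean base-to-tip
distance. Spine density is the number of spines per total arc length of
spiny dendrite.

## The synthetic generator

The generator defines the study conditions for every downstream test.

* **Tortuous neurites** are correlated random walks: each step of length
  `h` rotates the direction by a turning angle θ (folded normal) about an
  axis perpendicular to the march, at an azimuth drawn uniformly when
  `chirality_bias = 0`. The discrete curvature contributed by a turn is
  exactly `2|sin(θ/2)|/h`, so the angle spread is calibrated by solving
  `E[2|sin(θ/2)|]/h = κ_target` numerically — the realised mean curvature is
  unbiased for the target. Because `E[2|sin(θ/2)|] < 4/π`, targets above
  `1.2/h` are unreachable at step `h` and are truncated. A uniform azimuth
  makes left and right twists equally likely, so the expected signed
  torsion is zero — matching the observation that real neurites show no
  chiral bias.
* **Cohorts** default to the published case structure: four schizophrenia
  cases with per-case mean (SD) curvatures 0.46 (0.28), 0.47 (0.32),
  0.60 (0.34), 0.71 (0.36) µm⁻¹ and four controls at 0.33 (0.22),
  0.44 (0.21), 0.37 (0.21), 0.41 (0.23), about 500 segments per case
  (the published range is 415–880), an orphan fraction of 0.55 (published
  288/523 to 700/880), log-normal segment lengths (median ≈ 18 µm, so a
  segment carries enough nodes for stable estimates) and log-normal fibre
  radii (median ≈ 0.4 µm, range similar to the 0.1–3 µm analysed fibres).
  Per-segment curvature targets are normal draws truncated below at
  0.05 µm⁻¹ (the lowest published histogram bin). The drawn targets are
  emitted as a ground-truth table for parameter-recovery tests.
* **Spines** attach at arc-length-uniform positions with Poisson counts at
  the requested density — the simplest stationary model consistent with a
  per-length density. Stubby spines are short (0.3–1 µm) with radius
  roughly proportional to length; mushroom spines are longer (1–3 µm) with
  a neck that thins as the spine lengthens and a wider head, reproducing
  the wedge-plus-triangle shape of the length/minimum-radius scatter.
* **Phantom volumes** paint each chain as a radius-interpolated tube,
  blur with an isotropic Gaussian point-spread function and add Gaussian
  noise. Defaults — 0.05 µm voxels, PSF σ 0.12 µm (≈ 0.28 µm FWHM),
  bright tubes on dark background, contrast 900 against noise SD 20 —
  emulate a 180–300 nm-resolution synchrotron regime at desk-scale volume
  sizes (tests use ≤ ~130³ voxels; the design target is ≤ 256³). The
  published slices come with no quantitative noise or contrast statistics,
  so these are package choices, exposed in `raster_spec()`.

What the phantoms do *not* emulate: tomographic reconstruction artifacts
(rings, local-CT truncation), stain granularity, crossing or touching
neurites at high density, and intensity inhomogeneity along a neurite.
Passing the end-to-end tests therefore shows the tracer is correct on
clean tubular data, not that it would match human tracing on real tissue.

## Tracing

The automatic model-generation stage mirrors the classic
search → trace → refine design:

1. **Gradient vector flow** (`compute_gvf()`): the intensity gradient is
   diffused by the standard explicit iteration (weight µ = 0.1, 80
   iterations by default; stability requires µ ≤ 1/6). On a bright tube the
   field points inward from both flanks and vanishes on the axis.
2. **Seeding** (`find_seeds()`): voxels that are 26-neighbourhood local
   minima of the field magnitude *and* brighter than median + 6×MAD,
   thinned to ≥ 2 µm apart. The high brightness bar means pure noise never
   seeds a trace; tubes with usable contrast always do.
3. **Tracing** (`trace_from_seed()`): bidirectional march at 2 voxels per
   step. The local axis is the minor eigenvector of the structure tensor of
   3D Sobel gradients in a Gaussian-weighted window; each step re-centres
   on the intensity centroid of the perpendicular disc. Stops: intensity
   below median + 2×MAD, volume boundary, masked voxel, a turn sharper
   than 0.6 rad, or approach within the de-duplication distance of an
   existing chain. Chains shorter than 2 µm are discarded (this is what
   disposes of any seed that slipped into background).
4. **Masking** (`apply_mask()`): manually assigned somata and thick
   processes are painted as dilated capsules; the tracer never enters them.
5. **Refinement** (`refine_model()`): conjugate-gradient minimisation of
   − mean normalised node intensity + 1.0 × Σ‖second differences‖² +
   0.2 × Σ(spacing − target)², endpoints free, topology fixed. The
   objective trace is retained and must be non-increasing; if a line
   search fails on a rough image the best iterate is returned with a
   warning. Radii are (optionally) re-estimated afterwards by the half-max
   convention: the radius at which a spherical shell's mean intensity
   falls to background plus half the centreline excess.

None of the tracing constants is dictated by the data; all live in
`trace_params()` and were fixed once by calibration on helix phantoms of
known curvature and torsion: the end-to-end chain (rasterize → GVF → trace
→ refine → `segment_geometry()`) recovers helix curvature within 5%, the
torsion sign for both chiralities, and a centreline RMS error well under a
voxel. The manual-editing step of the original four-step protocol is out of
the automated path; an edited model can be supplied in its place.

## Statistics

`summarize_case()` produces mean / sample SD (n − 1 denominator) / n per
case for total curvature, orphan curvature and torsion.
`kruskal_wallis()` (rank H with tie correction, χ² approximation) compares
segment-level distributions across cases; `welch_t()` compares the
four-versus-four per-case means; `group_contrast()` reports the unweighted
group means, their ratio and percent increase. No multiple-testing
correction is applied, matching the source analysis; p-values are reported
raw with their test names. Histograms use left-closed bins anchored at 0
(0.1 µm⁻¹ default width). Scatter outliers (fibres thicker than 3 µm,
spines longer than 6 µm or with radius ratio above 2.7) are flagged, never
silently dropped.

On the published per-case means this machinery reproduces the printed
contrasts exactly:

```{r contrasts}
ref <- reference_case_summaries()
s <- ref[ref$group == "schizophrenia", ]
n <- ref[ref$group == "control", ]
group_contrast(s$orphan_curvature_mean, n$orphan_curvature_mean,
               labels = c("schizophrenia", "control"))
glance(group_contrast(s$curvature_mean, n$curvature_mean))
```

## Pipeline, reproducibility, degenerate inputs

`run_pipeline()` chains synth → (rasterize → trace) → geometry → stats from
a validated config (unknown keys are rejected by name), fans a single
master seed out to fixed per-stage sub-seeds, and writes a provenance
record (config hash, version, timestamps, output digests); identical config
and seed give identical digests. An optional blinded mode strips case
identities before geometry and re-joins them at stats, mirroring the
data-management / data-analysis role separation of the original study.

Degenerate inputs are handled explicitly: resampling with spacing beyond
the chain length returns the endpoints; segments with fewer than 3 (4)
resampled nodes report curvature (torsion) as absent; a zero minimum spine
radius makes the radius ratio undefined and flagged; zero spiny-dendrite
length with spines present is an error, 0/0 spine density is 0 with a
warning; identical values give H = 0, p = 1 in the Kruskal–Wallis test and
p = 1 in the zero-variance Welch case.

## Problem sizes

The bundled tests and the acceptance script run the full analysis at
deliberately desk-scale sizes chosen as representative rather than
exhaustive: phantom volumes around 10⁶ voxels (0.1 µm voxels over fields a
few tens of µm wide), cohorts of 8 × 500 segments, 10,000-replicate null
simulations for the Welch type-I check. All results quoted in the README
are computed by that code at those sizes.

## Known limitations

* The tracer is built and validated for sparse, Golgi-style contrast;
  dense tangles, touching fibres and reconstruction artifacts are out of
  scope, as is any interactive editing.
* Spine detection from images is not attempted; spines enter as annotated
  constituents (here, from the generator).
* Whether the original analysis averaged curvature over nodes or over arc
  length is not stated; this package averages over nodes (the resampled
  chain makes the two nearly identical) and exposes nothing else.
* The torsion estimator's sign convention (right-handed positive) is a
  package choice; only the symmetry of the torsion distribution about zero
  is scientifically meaningful here.
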