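---
title: "Quantifying immunological synapse patterning with synapsemap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying immunological synapse patterning with synapsemap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synapsemap)
```

## The analysis problem

When a T cell recognises peptide-MHC on an antigen presenting cell (APC), the
two cells form a tight conjugate and signalling proteins such as LAT, TCRzeta
or F-actin reporters reorganise at the contact interface — the immunological
synapse. In live-cell spinning-disk imaging (here emulated as 21 z-sections at
1 µm intervals every 20 s) these spatiotemporal patterns are diagnostic of
signalling outcome: a sustained central supramolecular cluster (cSMAC)
accompanies productive activation, whereas rapid transfer of sensor into a
µm-deep membrane invagination marks the termination of signalling.

`synapsemap` implements the full quantification chain for such data:

1. **couple tracking** — segment the GFP-positive T cell and the unlabelled
   APC, derive the contact geometry per frame, and set the reference frame
   t0 of *tight cell coupling*;
2. **pattern classification** — score interface enrichment against the 35%
   rule and assign one of six mutually exclusive accumulation patterns (or
   no accumulation) per frame;
3. **shape standardization** — morph each cell onto a canonical half-spheroid
   so sensor distributions are comparable voxel-by-voxel across cells, and
   derive interface-enrichment-region and central-core ratios;
4. **morphometrics** — interface diameter, cell width/length, neck and
   lamella scoring, shape factor, off-interface lamella detection;
5. **cohort statistics** — time-aligned percent-of-couples curves, the log2
   central/invagination ratio, cumulative off-interface lamellae, and exact
   condition comparisons.

Because per-couple manual classifications of real acquisitions are not
available as a machine-readable reference, every stage is validated against a
first-class **synthetic data generator** whose ground truth is closed-form.

## The tight-coupling reference frame

Couples are aligned in time at t0, the earlier of (a) the first frame at
which the T cell/APC interface has reached its full width and (b) 40 s after
first contact. "Full width" is a judgement call in manual scoring; here it is
operationalized as the interface diameter reaching at least 90% of its
running maximum over the following 120 s (the window that brackets the early
signalling burst). The whichever-first structure makes t0 insensitive to this
choice for rapidly coupling cells: any monotone plateau detector that fires
no earlier than the true full-width frame yields the same t0 whenever the
40 s rule wins. All cohort statistics run on the fixed grid −40 s … +420 s in
20 s steps; frames missing at a grid point contribute to neither numerator
nor denominator.

## Enrichment and the six-pattern cascade

The scalar gate is the 35% rule: the mean intensity over the *interface
shell* (the contact voxel set dilated one voxel into the T cell) is divided
by the mean over the cellular background (T cell voxels excluding the shell
and excluding the invagination search cylinder, so deep accumulations cannot
mask themselves); enrichment below 0.35 is `none`. The rule is applied to the
shell mean rather than a peak statistic — the less noise-sensitive reading.
Enrichment is a ratio, so all labels are invariant under global intensity
scaling.

Above the gate, the set of enriched voxels (≥ 1.35 × background after a light
in-plane mean filter; the filter never touches z so depth statistics stay
crisp on the coarse axial grid) is tested in a fixed precedence order:

| order | pattern | criterion (defaults) |
|---|---|---|
| 1 | invagination | centre-seeded enriched component deeper than 1.5 µm |
| 2 | central | ≥ 50% of enriched shell mass inside the central disc (relative radius < 0.5) and its centroid inside that disc |
| 3 | peripheral | ≥ 75% of enriched shell mass in the annulus, central-disc coverage < 50%, angular coverage ≥ 180° |
| 4 | asymmetric | enriched shell mass confined to a sector < 180° |
| 5 | lamellal | slab covering ≥ 50% of the interface area, extending 0.5–2.5 µm behind it |
| 6 | diffuse | everything else above the gate |

Depth-based structures are tested first because depth is the key
discriminator between the cluster (which stays at the interface) and the
invagination (which reaches micrometres into the cell). Two refinements over
a naive reading of the classical geometric criteria were necessary for the
cascade to be total and consistent: the central rule uses a mass fraction in
addition to the centroid (a symmetric annulus has its centroid at the origin
and would otherwise read as central), and the peripheral rule requires the
central disc to be mostly unoccupied (a uniform slab has exactly 75% of its
mass in the annulus by area alone). Diffuse doubles as the terminal
catch-all, which guarantees exactly one label for every enriched geometry.
Every threshold above is a named field of `classifier_params()`.

Angular statistics (coverage and minimal sector) are computed on 15°
occupancy bins, ignoring bins holding fewer than 1% of the enriched shell
voxels, which makes them robust to isolated noise voxels.

## Shape standardization

Each cell is reoriented with the interface facing up by a rigid rotation
carrying the interface normal onto the depth axis and the interface centre
onto a fixed reference point (single-landmark alignment plus normal
alignment), resampling intensities trilinearly onto an isotropic grid at the
finest acquisition spacing (0.25 µm). The azimuth about the normal is left at
the minimal-rotation solution; all downstream regions are azimuthally
symmetric, so this free angle does not affect the ratios.

Standardization then maps the cell onto a half-spheroid template
(64 × 64 lateral × 32 depth; large enough that the relative-0.5 central core
is resolved by ~15 voxels in radius) by *inverse* sampling: every template
voxel looks up the cell intensity at its (relative depth, relative radial
position within the cross-section at that depth, azimuth) coordinate, and the
result is normalized to a probability distribution (sum 1). Inverse mapping
rather than forward splatting is deliberate: it makes a uniform cell map to a
uniform template exactly, which is the testable null of the whole construct.
Per-slice boundary radii are estimated from per-azimuth voxel maxima and then
calibrated by the slice's area-equivalent radius, which is unbiased under
rasterization; sampling is pulled in one lateral voxel from the boundary,
0.4 µm below the interface plane and 0.75 µm short of the posterior pole so
template voxels never average extracellular partial-volume signal.

The **interface enrichment region** is the top decile of voxels of the
cohort-average distribution (ties at the cutoff broken by fixed grid order;
the average is pooled over whatever set of maps the analysis batch supplies).
The **enrichment ratio** is the mean probability over that region divided by
the mean over the whole template; the **central core ratio** uses the
cylinder of relative radius 0.5 and relative depth 0.5 anchored at the
interface centre. Both are exactly 1 for a uniform distribution and
N_template/N_region (≈ 10) when all mass sits in the region — closed forms
the test suite asserts to 1e-6.

Two numerical caveats are documented rather than hidden. First, when the
enrichment region is *estimated from the same maps it is applied to*, pure
noise inflates the mean ratio slightly (the top decile of a noisy average is
selected upward), and the standardization itself carries a small systematic
spatial pattern (the ~4% CV above) that any data-driven region partly
selects; zero-contrast calibration is therefore asserted on the scalar
interface/background enrichment ratio, which is unbiased, and map-ratio
comparisons are always made between cohorts scored against one common
region. Second, a couple whose interface normal is exactly
aligned with a lattice axis is a rasterization singularity: its structures
are rendered sharper than at any generic orientation, and ratio agreement
with rotated replicas is then ~6–10% rather than the ≤ 2% observed between
generic orientations. Real acquisitions are never lattice-aligned;
invariance claims apply to the generic case.

## Morphometrics

The midline is marched from the interface centre along the local mask
centroid direction in 0.15 µm steps, so it may bend with the cell; the cell
diameter profile is measured perpendicular to the local direction, cell width
is the profile maximum and cell length the total arc. A *neck* is a profile
minimum strictly between the interface and the widest point that is narrower
than both the interface diameter and the cell width; the lamella is scorable
only when the neck lies more than 1.3 µm from the interface, and the lamellal
length is that arc distance. The T cell shape factor is lamellal length over
interface diameter. Off-interface lamellae are residual components left by a
morphological opening (3-voxel radius on the isotropic reoriented mask) that
are longer than 1.3 µm and whose base lies farther than one interface radius
from the interface centre — the base rule keeps interface lamellae from
counting. A manual path accepts up to four annotated lines per frame (CSV)
and fills the same record. Note that neck positions along the optical axis
are quantized by the 1 µm z-step; the sharpness of the 1.3 µm rule is
therefore validated on couples oriented in the lateral plane, where the
0.25 µm pixel pitch resolves it.

## Cohort statistics

Percent-of-couples tables carry binomial standard errors by default
(√(p(1−p)/n), pooling couples); an alternative mode averages per-experiment
percentages and reports their SEM when experiment identifiers are available —
published error bars rarely state which convention they use, so both are
provided and named. The log2 central/invagination ratio uses the
Haldane–Anscombe continuity constant of 0.5 couples in both counts, keeping
the curve finite when one pattern's count reaches zero; the constant cancels
in the sign, so ratio > 0 if and only if central counts exceed invagination
counts. Condition comparisons use the exact two-proportion (Fisher) test per
timepoint — safe at cohort sizes of a few dozen couples — with Holm
adjustment along each pattern's time course. Cumulative off-interface curves
are the empirical CDF of first-flag times, scaled to percent.

## The synthetic generator

Cells are solids of revolution about the interface normal, evaluated in
physical coordinates, so an arbitrarily rotated couple is rendered exactly
rather than resampled: the T cell is a 5 µm sphere flattened by a 3 µm
contact disc facing a 4 µm APC (present only in a separate label channel, as
the APC is non-fluorescent in the GFP channel). Sensor accumulation adds
`contrast` × background (default contrast 2) inside per-pattern regions:
a central disc (relative radius 0.5, 1 µm deep), the same disc plus a 0.6 µm
tube reaching 2 µm deep (invagination — the opening accumulates sensor
too, which is also what lets a deep structure clear the shell-based 35%
gate), a thin cortical layer (diffuse), a full-width slab 1 µm deep
(lamellal), an annulus (peripheral) and a 120° annular sector (asymmetric).
The depths are chosen so each pattern stays on its side of the 1.5 µm
invagination criterion and spans at least two z-planes where it must.
Noise is the standard camera model Poisson(scale × clean)/scale +
Gaussian(0, σ), with defaults (scale 1 photon per unit at background 100,
σ = 5) giving shot noise of ~10% of the cellular background, and frames are
quantized to the camera bit depth. Interface growth (`grow_to_full_width`)
ramps the contact radius linearly over 80 s; shape events add early lamellae,
necks and off-interface protrusions with closed-form ground truth. Cohorts
draw each couple's per-timepoint pattern independently from programmed
frequency vectors, e.g. the effector scenario of 60% any-pattern, 42% central
and 13% invagination at +20 s.

What the generator does **not** emulate — photobleaching, drift, organelle
texture, partial-volume optics of a real PSF, multi-couple fields, and the
biological correlation of a couple's pattern across time (draws are
independent per timepoint) — bounds what green tests mean: they demonstrate
the correctness and calibration of the measurement chain on its stated
geometry, not classifier performance on real acquisitions.

## Problem sizes and determinism

The shipped test suite and the acceptance script size their simulations to
make sampling error negligible relative to the tested tolerances while
keeping a desk-scale footprint: 50 frames per label (64 × 64 × 21 voxels) for
classifier recovery, 10 000-couple label-only cohorts for frequency recovery,
500 replicate cohorts of 60 couples for standard-error calibration, and
2–4-couple rendered cohorts for end-to-end pipeline checks. Every stochastic
step derives from a single integer seed; identical configuration and seed
reproduce byte-identical outputs, and each CSV carries the MD5 hash of the
configuration that produced it.
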