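---
title: "Mapping cardiac fibre organization in the cervical vagus: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping cardiac fibre organization in the cervical vagus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vagusmap)
```

## Overview

`vagusmap` quantifies where functional fibre groups — laryngeal (L),
pulmonary (P), cardiac efferent (CE) and cardiac afferent (CA) — sit in the
cross-section of the mid-cervical vagus nerve, from two kinds of evidence:

1. **Anatomy (microCT arm).** Fascicles traced in ex vivo microCT, each with
   a centroid, area, organ label and fibre-type label (afferent = originates
   from the nodose ganglion; efferent = bypasses it).
2. **Function (sVNS arm).** Physiological responses (heart rate, end-tidal
   CO2, laryngeal EMG RMS) to spatially selective stimulation through each of
   the 14 circumferential electrode pairs of a cuff.

Both are brought onto the same unit-disc template, rotation-aligned per
animal, averaged into cross-animal atlases, and compared with angular
statistics and area/overlap fractions.

## Coordinate conventions and co-registration

Angles are degrees, 0° at the top of the displayed cross-section, increasing
clockwise; all modules share this convention. Electrode pairs are modelled as
points on the nerve boundary circle at their angular positions — the physical
cuff has two longitudinal rings, but a "pair" drives pads at the same angular
coordinate in both rings, so the rings collapse to one angle. Default pair
angles are equally spaced (`k * 360/14`); explicit angles can be supplied
when the hardware layout differs.

`project_to_template()` maintains, for each fascicle, the distance to its
nearest electrode, expressed in units of the nerve radius. With electrodes on
the circular boundary this has a closed form: keeping the fascicle's polar
angle and dividing its centroid radius by the nerve radius preserves the
normalized nearest-electrode distance exactly (law of cosines: the distance
between a point at radius `r` and a boundary point depends only on `r/R` and
the angular separation once lengths are in units of `R`). The test suite
verifies the distance-preservation property to 1e-9 rather than trusting the
derivation.

The nerve boundary radius for synthetic data is derived from the reported
cross-sectional *area* of 2.68 mm² (radius ≈ 0.92 mm). The separately
reported ~6.6 mm "diameter" is inconsistent with that area (it would imply
~34 mm²) and is likely an outer/stretched measurement; we follow the area
since the template is an area-preserving disc.

## Rasterization, rotation and atlases

Group maps are binary W×W rasters (default `W = 256`; the resolution is a
package choice — at 256 the pixel quantization error of a centre-of-mass
angle is below 0.5° for typical blobs, and every map operation is O(W²)).
Each fascicle is painted as a disc of equivalent radius `sqrt(area/pi)`;
a pixel is 1 iff its centre falls inside any disc of the group and inside the
disc mask. Organ labels map to groups as: cardiac → CE (purely cardiac
fascicles were found to be exclusively efferent), cardiopulmonary → CA *and*
P (they carry afferent fibres of both organs), laryngopulmonary → L and P.
The laryngopulmonary double membership is an assumption — such fascicles
contain fibres of both organs, and the alternative (an own fifth map) would
dilute both the L and P atlases.

Rotation alignment uses the value-weighted centre of mass of the CE map
(area-weighted across all CE fascicles when there are several); each animal's
four maps are rotated by the negation of that angle with nearest-neighbour
resampling. Nearest-neighbour is chosen deliberately: atlas semantics need
binary inputs, and interpolation would manufacture fractional presence at
blob edges. The cost is ~1–2% area non-conservation for small blobs, which
the tests bound.

Atlases are pixel-wise means of the rotated per-animal maps. For binary
inputs the mean *is* the normalized atlas: 0 = no animal, 1 = all animals.
Response atlases average per-animal maps that are already max-normalized to
[0, 1], then divide by their own maximum so the atlas peak is 1; this is our
reading of "normalizing to 1" for response data, where per-animal magnitudes
are not commensurate.

## Response extraction and back-projection

Per-pair responses are percent changes versus baseline. The baseline is the
mean signal over a window immediately preceding stimulation onset; the
response statistic is the extremum (signed value of largest absolute
deviation from baseline) of the 2-s moving-average-smoothed signal within a
response window after onset. The extremum, not the window mean, is used so
the same code handles immediate efferent responses and afferent reflex
responses delayed by brainstem-loop latency; both the baseline and response
windows are arguments. The pipeline defaults use the *second half* of the
preceding off period as baseline — a delayed reflex returns to baseline
`delay + on_duration` after onset, so the early off period of the *previous*
epoch can still carry response — and `on + off/2` as the response window.
Multiple epochs of the same pair are averaged.

Back-projection subdivides the disc into 14 angular Voronoi sectors (pixel →
nearest pair angle, ties to the lower index) and paints each sector with the
pair's |response| normalized by the maximal |response|. Maps carry magnitude
only; polarity stays in the `pair_response_set`. The "effective pair" count
(pairs reaching ≥75% of the maximal absolute response) summarizes spatial
selectivity.

## Angular statistics

CoM angles are compared across groups with one-way ANOVA plus Tukey HSD (or
Bonferroni) on the rotation-aligned angles, per technique. Angles live on a
circle, so they are unwrapped to a linear scale first — **about each group's
own circular mean**, not about 0. Unwrapping about 0 would split the CA
group, whose rotated-frame CoMs sit near ±180°, across the wrap point and
destroy the CE–CA comparison by construction; unwrapping about the group
mean keeps within-group spread linear wherever the group sits. A
Watson–Williams circular ANOVA is available behind `circular = TRUE` (with
Bonferroni-adjusted pairwise tests, since Tukey is undefined there); it is
not the default because the linear ANOVA on aligned angles is the
conventional analysis for this design and the two agree for concentrated
groups.

The per-animal CA–CE separation is summarized as arithmetic mean ± SD of the
per-animal circular differences, linearized about their cohort circular
mean. The naive alternative — folding each difference into [0, 180] — cannot
exceed 180 and therefore biases the mean of diametrically opposed groups
downward by ≈ 0.8·SD (folded mean ≈ 155° for a true 180° separation with 30°
spread); it also caps the SD. The linearized statistic estimates a true 180°
separation without bias, matching how a mean separation of ~179° with an SD
of ~55° can be reported at all.

ANOVA on grouped CoM angles is a fixed-effects comparison of group *means*;
with small cohorts (5–10 animals) it has the usual small-sample caveats, and
the package intentionally does not reproduce any particular experiment's
p-values — those depend on the real animals.

## Overlap matrices

`overlap_matrix()` binarizes maps at threshold τ and reports, as fractions of
the total disc area, per-group areas (diagonal) and pairwise shared areas
(off-diagonal). Per-animal binary maps need no thresholding choice (any
τ ∈ (0, 1] selects the painted pixels; the default 0.5 works). For atlases
τ = 0.5 means "present in at least half the animals"; note that a group of
small, variably placed fascicles (CA in particular) can have *no* pixel
shared by half the animals, so atlas-level relative overlaps can be
undefined for it — the pipeline therefore reports the CA-with-CE relative
overlap from per-animal binary maps. Relative overlap is asymmetric by
design: `100 · overlap(A,B) / area(A)` ("how much of A is inside B"),
reported half-up-rounded to integer percent as is conventional. The identity
`rel(A,B)·area(A) = rel(B,A)·area(B)` holds up to that rounding and is
tested.

## The synthetic cohort: what it emulates, and what it does not

The generator's defaults are the study conditions, not tuning knobs:

| parameter | default | basis |
|---|---|---|
| fascicle counts (mean ± SD per class) | cardiac 1.2 ± 0.5, laryngeal 10.2 ± 1.8, pulmonary 10.4 ± 1.9, cardiopulmonary 1.4 ± 0.6, laryngopulmonary 6 ± 2 | reported composition |
| fibre-type mix | cardiac 100% efferent; cardiopulmonary afferent; laryngeal 82/0/18, pulmonary 0/88/12, laryngopulmonary 13/57/30 (eff/aff/mixed %) | reported proportions |
| nerve area | 2.68 mm² | reported |
| afferent–efferent separation | 180° | bimodal opposite-sides organization |
| angular spread | 25° | chosen once: gives per-animal CoM separations with SD ≈ 30–40°, comparable to the reported between-animal variability |
| fascicle equivalent radii | 0.04–0.09 mm | chosen once: ~29 non-overlapping discs occupy a realistic 15–20% of the cross-section and remain placeable by rejection sampling |

Placement draws a lobe per fascicle (efferent-type fascicles about the
animal's efferent axis, afferent-type about the axis + separation, mixed on
either side with equal probability), a wrapped-normal angle, and an
area-uniform radius, rejecting positions that overlap previously placed
discs or cross the boundary; large fascicles are placed first. Generation is
fully deterministic given `(seed, animal_index)`.

The stimulation simulator uses the minimal activation model that reproduces
amplitude-dependent selectivity: a step threshold per functional group
(laryngeal 0.008 mA, pulmonary 0.5 mA, CE 0.8 mA, CA 4.0 mA — preserving the
reported ~100× cardiac/laryngeal threshold ratio, with each protocol's
starting amplitude just above its own target's threshold) and a Gaussian
angular weight `exp(-d²/(2σ²))` with σ = 20°, a free parameter (no
quantitative selectivity width is reported; 20° makes 1–3 of the 14 pairs
"effective", consistent with the reported 2.0 ± 1.7). Pathways are gated by
vagotomy state: the direct efferent HR response requires an intact right
vagus; the afferent reflex (delayed 10 s, polarity fixed per animal, drawn
6:4 tachycardia:bradycardia) survives right distal vagotomy, and bilateral
vagotomy abolishes reflex bradycardia (left-vagal efferent loop) but not
reflex tachycardia (sympathetic chain). Gains are set so a typical best-pair
pre-vagotomy HR response is ≈ −8%. Traces are sampled at 10 samples/s
(sufficient for epoch means; raw kHz acquisition is out of scope) with
additive Gaussian noise (HR 0.5 b.p.m. by default).

What passing tests on synthetic data *show*: the pipeline recovers the
organization the generator put in (180° separation, exclusive CE regions,
selective pairs) through the full co-registration → mapping → statistics
chain, with correct determinism, inversion and oracle-checked primitives.
What they do *not* show: performance on real data with non-circular nerve
boundaries, tissue deformation between in vivo and ex vivo states,
non-Gaussian angular selectivity, correlated physiological noise, or
segmentation error — none of which the generator models.

## Numerical choices and degenerate inputs

- Ties (equidistant electrodes, sector boundaries) go to the lowest index;
  deterministic and documented.
- Centre-of-mass of a map with radial symmetry is degenerate: radius ≈ 0 and
  the angle is meaningless; such CoMs carry `degenerate = TRUE` and report
  angle 0. The degeneracy threshold is one pixel (2/W).
- Empty maps: an empty CE map cannot be aligned (error); an empty group map
  elsewhere simply contributes no CoM and zero area.
- A group with fewer than two CoMs is excluded from the ANOVA with a
  warning; relative overlap is an error for a zero-area reference group.
- Rejection-sampling placement fails loudly after 4000 retries per fascicle
  with advice to lower counts or enlarge the nerve.
- Reported problem sizes: the bundled end-to-end analyses use 5 traced
  nerves + 10 simulated sessions at W = 256, and the statistical calibration
  checks use 1000 label-shuffle replicates; both sizes are the package's
  default study conditions.

## Limitations

- The template is a circle; real cross-sections are elliptical and the
  co-registration inherits whatever distortion the upstream segmentation
  introduced.
- Rotation alignment uses a single landmark (the CE CoM); no deformable
  registration between animals is attempted, so atlas spread conflates
  biological variability with alignment error.
- Back-projection attributes a pair's response to its entire sector;
  it cannot resolve radial structure.
- The ANOVA treats aligned angles as linear data; for highly dispersed
  groups prefer `circular = TRUE`.
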