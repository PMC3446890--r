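---
title: "Transcriptome tomography: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptome tomography: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txtomo)
```

## The measurement model

Slab tomography of expression trades in-plane resolution for breadth: a
whole organ is serially sectioned into ~1-mm slabs ("fractions") along one
body axis, every slab is homogenised, and its RNA pool is measured in bulk,
one chip per slab. One sectioning direction therefore yields a 1-D profile
per probe. Repeating the sectioning on genetically identical specimens
along other directions and combining the profiles tomographically gives an
isotropic 3-D density map for every probe simultaneously — tens of
thousands of maps from a few dozen chips.

`txtomo` models this as follows. Space is an isotropic voxel grid (100 µm
by default — fine enough to resolve 1,000-µm slabs ten-fold, coarse enough
that whole-brain arrays stay desk-scale); tissue support is a boolean mask.
A sectioning series is a unit normal, a slab width, an offset and a
fraction count; voxel membership uses the voxel-centre rule on half-open
intervals, so each covered voxel belongs to exactly one fraction and every
geometric predicate is exactly testable (no partial-volume weights).
Fraction `k` of series `s` measures the *mean* of the density field over
its in-mask voxels: chip intensity tracks the concentration of a
transcript in the slab's RNA pool, not the total amount (a `sum` statistic
is available for sensitivity analysis). Measurement noise, when simulated,
is multiplicative log-normal — the standard first-order model for intensity
data — with log-sd `sdlog`.

## Reconstruction and the cutoff filter

Reconstruction is single-pass pseudo-back-projection: each fraction's
value is painted onto all of its voxels, and the per-voxel values from the
different series are averaged with equal weights (a volume-weighted
variant is deliberately out of scope; with near-equal slab volumes it
differs negligibly, and the unweighted mean is the simplest faithful
reading of "averaging the densities in the voxels"). Maps are defined only
on the *coverage volume* — voxels assigned a fraction in every series — so
that every voxel's value averages the same number of measurements.
Accumulation is in double precision in fixed voxel order; reconstruction
of a constant field returns the constant to better than 1e-12 relative
error, which the test suite asserts.

The *80% cutoff filter* retains voxels with value at least
`keep_fraction × max(v)` over the coverage volume (`keep_fraction = 0.8`).
An alternative reading — threshold at the 0.8 *quantile* of positive
values — is implemented behind `method = "quantile"` but is not the
default: on 1,000-µm phantom spheres it retains the top fifth of all slabs
touching the sphere and inflates the equivalent diameter of the selected
region almost four-fold, which is far outside the plausible behaviour of a
high-density filter, whereas the max-referenced threshold inflates it by
~1.5×. Quantification never uses the 8-bit export (`to_8bit()` exists for
visual comparison only; it rounds half away from zero, so half of the
maximum maps to 128).

## The sectioning design

The reference design has three orthogonal series along x/y/z (sagittal,
coronal, horizontal; 9/13/6 fractions) and three oblique companions
(10/16/7 fractions), all 1,000 µm wide — 61 fractions. Two quantities the
design leaves open are parameters with defaults:

* **Oblique tilt.** "Slightly oblique" is taken as a 10° rotation of each
  orthogonal normal about a fixed perpendicular axis (S about z, C about
  x, H about y); the angle is configurable per design.
* **Offsets.** Each series' slab span is centred on the mask's projection
  onto its normal; the physical offsets of a real instrument run are not
  recoverable from the data.

A geometric consequence worth understanding: a tissue that fits the
9×13×6-mm orthogonal spans projects onto a 10°-oblique coronal normal by
at most ~14 mm, so the 16-fraction oblique coronal span necessarily
overhangs and its two edge slabs contain no tissue. `txtomo` treats such
empty fractions as measuring 0 — they hold no RNA, and because no voxel
maps to them they cannot influence any reconstruction — while
`on_empty = "error"` enforces the strict every-fraction-holds-tissue
contract for real data validation. Downstream, `drop_empty_fractions()`
removes the corresponding all-zero chip columns before normalisation or
correlation analysis, which would otherwise be degenerate.

## The phantom experiment

Spatial accuracy is measured by phantoms: uniform-density spheres of
1,000 µm placed uniformly at in-mask voxel centres, sectioned noiselessly
through every template, reconstructed, and thresholded. Per sphere we
report the true-positive overlap (per cent of the sphere's voxelized
volume covered by the suprathreshold region — the full sphere volume is
the denominator, so spheres protruding past the tissue boundary are
penalised, which is exactly the failure mode of peripherally placed
phantoms) and the diameter ratio (equivalent-sphere diameter of the
region, (6V/π)^(1/3), over the sphere diameter; connected components are
not pruned, since the method itself imposes no connectivity).

Under ideal, parametrically generated templates the experiment is
forgiving: essentially every in-mask sphere is recovered at ≥5% overlap,
none is missed outright, and regions inflate ~1.5× in diameter (the slab
intersection geometry of equal-width slabs). Empirical pipelines built on
templates registered from several physical specimens carry
few-hundred-µm inter-series misalignment, which inflates reconstructed
regions further and produces a tail of peripheral failures; modelling that
registration scatter is out of scope here, so the phantom statistics this
package computes characterise the geometric method itself, not any
particular instrument run. The full-scale run (1,366 spheres at 100-µm
voxels) is what `scripts/acceptance.R` recomputes.

## Probe statistics

All statistics operate on `log2(intensity + 1)`; the +1 offset stabilises
low intensities after per-chip normalisation, and the log base only
rescales, never reorders, any statistic used. Per-chip normalisation
divides each fraction's column by its 75th-percentile intensity (the
common chip-normalisation target; the median is available by flag).
"Total probes" are those with at least one present flag.

Because slabs from the orthogonal and oblique groups overlap anatomically,
the highest-correlation cross-group fraction pairs behave as "slightly
different" biological replicates. Pairing is greedy on descending Pearson
r with exact ties broken by anatomical order (same body axis, closest slab
indices); unpaired fractions are excluded from the ANOVA. Each pair is one
level with two observations in a per-probe one-way ANOVA (the F statistic
is computed vectorised across probes and is cross-checked against
`stats::aov` in the tests); p-values are Benjamini–Hochberg adjusted
across probes into `V`. A probe with zero variance gets p = 1. `I` is the
median log2 intensity over all fractions; groups are `I/i` by strict
comparison with the median of all probes' `I` (ties to `i`, so the split
halves the set up to ties) and `V/v` by `V < 0.05`. The `I`-vs-`V`
independence diagnostic is the correlation of `I` with `log10(V)`,
reported by `glance()` rather than tested, since the scale of that
correlation is a convention.

## Area quantification

Areas are 500-µm voxelized spheres at given centroids (with optional
bilateral mirroring about the mid-sagittal plane, x = 0 for the synthetic
brain), marker-gene suprathreshold regions, or set combinations
(intersection of positive markers minus union of negative ones). The area
density rule is literal: the sum of map values at or above the cutoff
threshold inside the area, divided by the area's *full* voxel count —
sub-threshold voxels dilute the density rather than shrink the area. The
`raw` mode (plain mean, no threshold, no per-gene normalisation) is used
for cross-dataset comparison; bilateral areas average the two sides before
the log transform. Cross-area t-tests treat voxels as observations;
back-projected neighbouring voxels are strongly dependent, so these
p-values are descriptive, not independence-respecting inference (the
α = 0.01 convention is annotated in the output). Dataset comparison picks
per gene the probe with the highest mean intensity on each platform,
correlates log2 values over shared (gene, area) pairs, and reports a CV
curve over 0.02-quantile windows of the reference values with 0.1%
trimmed from both tails of each window.

## The synthetic study generator

`synthetic_study()` emulates the reference conditions: the brain-shaped
mask (union of a cerebrum ellipsoid, a posterior cerebellar bulge and a
ventral stem, x-mirror symmetric, bounding box within 9×13×6 mm), the
six-series design, per-probe baselines drawn log-normally (median ~500,
log-sd 1 — a typical chip intensity spread), measurement noise at
`sdlog = 0.1`, and planted spatial patterns on a chosen fraction of probes
(default 10%), cycling through an ellipsoidal region marker, a 3.5-mm
focal sphere and a smooth axis gradient. The pattern fixes the *shape* of
a probe's fraction profile; `effect_size` sets its *measured amplitude* —
the noiseless log-signal sd across fractions — so that effect and noise
are on the same scale and `effect_size = 4 * sdlog` means signal four
times the noise at the observation level (defining the effect before slab
averaging would make its realised magnitude depend on pattern size in an
uninterpretable way). All randomness derives from one master seed through
named substreams (patterns, baselines, noise), so studies are
byte-reproducible.

What the generator does *not* emulate: probe cross-hybridisation, chip
spatial artifacts, anatomical texture within structures, inter-specimen
variability, and template registration error. Tests passing on synthetic
studies therefore demonstrate the correctness and operating
characteristics of the algorithms under the stated noise model, not
robustness to those real-data effects.

## Problem sizes and numerical conventions

The test suite exercises oracle equivalence (naive per-voxel loops) on
grids up to 28³, the conservation identity at 200-µm voxels, the
full-scale phantom (1,366 spheres, 100-µm voxels, ~30 s), and statistics
on 10,000-probe null and 2,000-probe power studies at 200-µm voxels —
sizes chosen so the whole suite runs in about a minute on one CPU while
still using the full reference design. Degenerate inputs fail loudly and
specifically: empty masks, empty templates (strict mode), empty joint
coverage, all-zero maps under the cutoff, constant fractions in
correlations, overlapping replicate groups, centroids outside coverage.

## Known limitations

* Single-pass back-projection is the method; no iterative or regularised
  inversion, and axial resolution is bounded by slab width.
* The tilt angle and series offsets of any real instrument run must be
  supplied; defaults are stated conventions, not estimates.
* Voxelwise t-tests ignore spatial dependence (documented as
  descriptive).
* NRRD support covers the 3-D raw-encoding scalar volumes the package
  writes, not the full format.
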