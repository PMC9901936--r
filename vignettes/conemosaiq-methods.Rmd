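---
title: "Methods: quantifying cone mosaics and double-positive reporters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying cone mosaics and double-positive reporters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

conemosaiq implements the quantification side of an F0 CRISPR screen of
photoreceptor identity in the larval zebrafish retina: per-cell reporter
fluorescence measured inside eroded marker masks, control-calibrated
double-positive classification, per-field density statistics compared
with rank tests, and the filter layer used on photoreceptor
expression matrices. A synthetic-data module generates retinal fields
and count matrices with known ground truth, so every stage is testable
without microscopy or sequencing data. This vignette records the model,
the conventions, and the design decisions, in that order of importance.

## The measurement chain

A field is a 64 µm × 64 µm patch of central retina, imaged as a
two-channel z-stack (red subtype marker, green GFP reporter) and
collapsed by maximum-intensity projection over the planes containing the
photoreceptors (`max_project()`; plane selection is a user decision, as
it is at the microscope).

Three steps make per-cell GFP comparable across fields:

1. **Image-wide min–max normalization** (`normalize_channel()`): the
   green channel is mapped linearly to [0, 1] over the whole image.
   The operational content is scale invariance — multiplying raw
   intensities by any a > 0 (detector gain) leaves every downstream
   mean, threshold and classification unchanged. This invariance is
   regression-tested. A constant image is defined to normalize to all
   zeros (with a warning): zero is the conservative value for a
   signal-free field. Normalization is computed on the projected image,
   not per z-plane.
2. **Segmentation of the red channel** (`segment_reference()`): the
   bright, well-separated marker channel is segmented, and its labels
   are used as masks for the green channel — segmenting green directly
   is unreliable exactly in the condition of interest, when extra
   green cells appear. The built-in segmenter is a deterministic
   stand-in for learned segmenters plus manual correction: Gaussian
   smoothing, Otsu (or fixed) threshold, 8-connected components,
   optional distance-transform watershed splitting, minimum-area
   filter. Labels are canonically renumbered in raster order of each
   region's first pixel so repeated runs are bit-identical. External
   masks (e.g. from Cellpose) can be imported as TIFF instead.
3. **Per-label erosion before averaging** (`erode_labels()`): each
   label is eroded by a disk of radius 10 px at the reference
   resolution of 16 px/µm (0.625 µm) before the normalized green is
   averaged over the remaining pixels. Optical blur bleeds green signal
   from adjacent GFP-positive cells across cell borders; the eroded
   core is insulated from it. A regression fixture (a red-only cell
   ringed by bright green neighbours, PSF σ = 10 px) shows the
   uneroded mean crossing the classification threshold while the eroded
   mean stays below it. Each label is eroded on its own binary copy, so
   touching cells never interact. Cells eroded to nothing are flagged
   invalid and excluded from fractions rather than counted negative —
   counting them negative would bias toward the null. The structuring
   element is a disk by default (isotropic; the source protocol does
   not name an element) with a square option. When fields are simulated
   or imaged at another resolution, the radius is converted by physical
   size (`scale_erosion_radius()`), e.g. 2 px at 4 px/µm; an erosion
   radius is a physical quantity, not a pixel count.

## Threshold calibration

The source workflow chose a classification threshold "from the
distribution" of control-cell GFP values — a threshold of 0.195 exceeded
by ~5% of control L cones (0.275 for S cones). Plot-reading is not an
algorithm, so `calibrate_threshold()` uses the principled surrogate: the
smallest observed control value t such that the fraction of control
values strictly above t is ≤ α (nearest-rank (1−α) quantile, α = 0.05
by default). Applied back to its own calibration set, the threshold's
exceedance is ≤ α by construction; this self-consistency is tested. The
published fixed thresholds remain available via `fixed_threshold()`.
"Exceeds" is strict by default; a value exactly at the threshold is
negative (configurable).

One property of quantile calibration deserves a record. If the control
population truly contains a fraction f ≈ α of genuine positives, the
(1−α) quantile sits on a knife edge: sampling fluctuations that push the
realized control positive rate above α move the threshold *into* the
positive cluster, and sensitivity in the test group drops to roughly
α/f — independent of how well separated the intensity clusters are.
With ~1200 pooled control cells this breaks a 3-standard-error recovery
band in roughly 15% of simulated cohorts. The acceptance suite therefore
simulates cohorts whose control fields contain *exactly* 5% double
positives (the generator's `exact_counts` mode — the stated world of the
recovery criterion), where recovery is clean. A hand-placed threshold at
the valley of a bimodal distribution, as in the source workflow, does
not have this instability; users calibrating on controls with a
substantial true-positive rate should prefer `fixed_thresholds` or a
larger α.

Double-positive fractions are computed per field, and fields (retinas)
are the experimental units entering the group comparison. GFP-only cells
are counted by excluding green segments that overlap a red label on
≥ 50% of their pixels (`count_gfp_only()`; the threshold is
configurable), mechanizing the manual "GFP only" counts. Densities are
reported per field and per mm² (a 64 µm field with 100 cells is
24414.06 cells/mm²). An empty field has density 0 but a *missing*
double-positive fraction, never 0.

## Group statistics

`kruskal_wallis()` implements the tie-corrected statistic

H = [12/(N(N+1)) Σᵢ Rᵢ²/nᵢ − 3(N+1)] / [1 − Σₜ(t³−t)/(N³−N)]

with mid-ranks, p from χ²(k−1), and the convention H = 0, p = 1 when
all observations are tied (the statistic is otherwise undefined; the
convention is conservative). Significance follows the screen's p < 0.01
rule. `conover_iman()` provides the post hoc pairwise tests

t = (R̄ᵢ − R̄ⱼ) / √[S² (N−1−H)/(N−k) (1/nᵢ + 1/nⱼ)],
S² = (Σ R² − N(N+1)²/4)/(N−1)

two-sided on N−k df, Bonferroni-adjusted over all k(k−1)/2 pairs
actually performed. When groups are perfectly separated H equals its
maximum N−1 and the variance factor vanishes; the pairwise p is then 1
(an H supplied externally that exceeds N−1 is clamped, with a warning).
Group summaries use the n−1 standard deviation, fold change
mean/mean(control), and percent change 100·(control−group)/control,
with missing (not infinite) effects when the control mean is 0.

The χ² tail is an approximation. At N ≤ 8 its deviation from the exact
permutation distribution reaches ~0.19 in the mid-distribution, but
stays within 0.05 throughout the significance tail (p ≤ 0.1), the only
region the screen's decision rule consults; the property test asserts
exactly that, over the full enumerated null support.

## Expression-matrix layer

`fpkm()` is the plain transform counts/(length/10³)/(total/10⁶).
`aggregate_genes()` sums duplicated opsins (presets: M-opsin =
opn1mw1–4, L-opsin = opn1lw1–2). The differential-expression *filter* —
the part of the workflow that is a stated rule rather than a model fit —
is `deg_filter()`: a gene passes if fold-enrichment > 1.5, p < 0.01,
adjusted p < 0.1, and positive raw counts in strictly more than 50% of
the enriched group's samples (at n = 6 that means ≥ 4). All
inequalities are strict, matching the printed criteria. Fold-enrichment
is the ratio of group mean FPKMs with a 0.01 FPKM pseudocount in the
denominator when the smaller mean is zero (the base quantity is not
defined in the source; the pseudocount only guards division). In
rod-vs-cone comparisons the fold criterion is dropped, so differences
carried by one or two cone subtypes are not masked. "Positive reads"
means raw count > 0, evaluated on counts, not FPKM (identical in
practice).

Per-gene p-values can be ingested from a dedicated count-model fit and
are then used unchanged; reimplementing such a model is out of scope.
The built-in stand-in (`per_gene_stats()`) is a Welch t-test on
log₂(FPKM+1) with Benjamini–Hochberg adjustment, clearly labelled as
such. Genes with zero variance in both groups get p = 1 by convention —
literally, even in the degenerate case of two different constants,
which a variance-based test cannot assess. Under a null synthetic
matrix the stand-in's p < 0.01 rate is verified to sit within binomial
bounds of 0.01.

`tf_expressed()` retains a transcription factor when at least 20% of
all samples (7 of 35 in the reference design) have positive counts —
inclusive, unlike the strict DEG fraction, matching "at least 20%".
`rod_contamination()` scores each sample's rhodopsin FPKM as a
percentage of the mean rhodopsin FPKM over rod samples, so rods sit at
100 and a cone sample with a fraction c of rod-derived reads sits near
100c; bands are low < 5, high > 15, moderate between. The source states
the idea and the bands but not the formula; relative-to-rod-mean is our
interpretation, and it is invariant to jointly rescaling all library
sizes.

## The synthetic world

`generate_field()` renders what the measurement chain assumes: a
64 µm field (1024×1024 px at 16 px/µm by default) with red-marker and
green-only cells placed by hard-core rejection sampling (minimum
spacing 3.4 µm; a jittered hexagonal mode exists for stricter
regularity), a specified double-positive fraction (Bernoulli per cell,
or exactly round(f·n) under `exact_counts`), per-population Gaussian
intensities on a 12-bit detector scale, a single Gaussian PSF, and
additive background plus Gaussian noise. Cell counts default to ~100
red and ~60 green-only cells per field — the source reports no density
table for controls; these are inferred from figure-level count
differences and are configurable, not asserted. Red-only cells carry a
baseline green signal (mean 5% of the green-only mean), modelling the
observed minority of control cells near threshold and making
classification non-trivial. Double-positive green defaults to the
green-only distribution, so classification difficulty is tunable.
Intensity means default to 2000 ± 300 (mid-range of the 12-bit scale,
SNR ~ 10 over background 80 ± 20) — typical confocal orders of
magnitude; their absolute values are irrelevant downstream by the
scale-invariance property.

Cells are hard-edged disks. That is deliberate: disks are sufficient to
exercise segmentation, erosion, averaging, calibration and
classification, and they admit an exact brute-force rasterization
oracle. The generator does not emulate real cell morphology, z-optics
beyond one PSF, photobleaching, chromatic aberration, or mosaic
defects; a green test therefore establishes the correctness of the
measurement chain, not the realism of any biological conclusion.
`generate_cohort()` derives per-field seeds deterministically from a
base seed, group name and field index; identical spec + seed is
bit-identical everywhere (fixed RNG kind, restored afterwards).

`generate_expression()` draws negative-binomial counts (dispersion 0.2
by default, the magnitude typical of bulk replicates; 0 gives Poisson)
around a per-subtype mean profile: flat baseline, planted
per-subtype enriched sets (default 10-fold, anchored by the canonical
opsins, subtype-exclusive), columns scaled to a target library size
(2×10⁶, the scale of low-input bulk libraries), and rod contamination
as a count-level mixture: a fraction c of each cone sample's expected
counts comes from the rod profile. The mixture is the simplest
generative model consistent with assessing contamination via rhodopsin,
and it makes the contamination score's expectation 100c by
construction. The default design is the study's: rod/UV/S/M/L with
6/5/6/7/6 replicates.

## Numerical conventions worth knowing

- Erosion treats pixels outside the image as background, so cells
  touching the field border erode from the border too (conservative).
- Otsu's threshold uses 256 bins over the observed range; ties broken
  toward the lower threshold.
- Watershed splitting seeds markers from the level set at 0.8 of each
  component's distance-transform maximum — on a raster grid the waist
  between two touching disks is thicker than the continuous formula
  suggests, which is why the level is as high as it is. Splitting is
  off by default.
- The acceptance cohorts run at 256×256 px (4 px/µm) with the erosion
  radius converted by physical size (2 px); a literal 10 px erosion at
  that resolution would be 2.5 µm, wider than any feasible cell radius
  at realistic density.
- Calibration requires ≥ 20 control values (below that the quantile is
  too unstable to be meaningful).
- TIFF I/O is a minimal baseline codec (uncompressed, little-endian,
  multi-page, 8/16/32-bit) written for this package because the
  installed R stack has none; label masks widen to 32-bit when a label
  exceeds 65535. Interoperability with standard readers was verified
  during development.
- Configs are single JSON documents; unknown keys are rejected so a
  typo in a threshold name cannot silently fall back to a default.

## Limitations

The segmenter is a transparent stand-in, not a learned model; on real
micrographs Cellpose-quality masks should be imported. The Welch
stand-in is not a count model and should not be quoted as one — ingest
dedicated per-gene statistics for publication-grade DEG lists. The
synthetic generator's realism is bounded as described above. No 3-D
segmentation, no mosaic-regularity statistics, no regional
(dorsal/ventral) analysis.
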