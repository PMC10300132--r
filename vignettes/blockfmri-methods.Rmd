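---
title: "Methods: simulation, GLMs, functional ROIs and searchlight RSA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, GLMs, functional ROIs and searchlight RSA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(blockfmri)
```

This vignette documents the models, parameter choices and numerical
conventions behind `blockfmri`, and what the synthetic-data tests do and do
not establish about real data.

## The study design being modelled

The package targets a comparative visual-category experiment: six stimulus
conditions (dog faces, dog bodies, human faces, human bodies, inanimate
objects, grid-scrambled controls), 30 images each, shown in 12-s blocks of
5 images, three blocks per condition per run, two runs of roughly five
minutes at TR = 1 s. Block order is randomized under the constraint that a
condition never repeats back to back; blocks are separated by visual
baselines jittered uniformly on 3–7 s; each image appears exactly once in
the session.

Two design choices were genuinely open and are resolved as follows:

* **Baseline placement.** A leading baseline precedes the first block and
  one baseline follows every block (19 baselines per run of 18 blocks). The
  leading baseline gives the GLM a pre-stimulus reference level.
* **Run length.** The run ends when the last baseline ends, rounded up to a
  whole number of TRs, so run length is an emergent quantity (typically
  305–330 scans) rather than a fixed target.

Jitters are continuous (not TR-locked); block onsets are kept at sub-TR
precision and handled by convolution on a fine grid (dt = TR/16), with scans
sampled at mid-TR.

## Synthetic stimuli

Stimuli are coloured shapes on a uniform mid-grey background (RGB
128,128,128): faces are near-round ellipses covering ≈ 58% of the frame,
bodies elongated ellipses covering ≈ 29% — reproducing the spatial-extent
asymmetry that real face/body cut-outs show — and objects are rectangles
matched half to the face and half to the body extent. Hue bands differ by
species and category so the property ANOVAs have realistic structure.
Scrambled images are tile permutations of source images drawn equally from
the five other conditions, on an 8×8 grid (the grid size is a convention;
any size that destroys global shape while preserving the colour histogram
would do). Because foreground and background are exact, spatial extent is
exactly computable; a background-match tolerance parameter (default ±2
intensity levels) exists for imported photographs.

For the property measures, "contrast" is the population standard deviation
of the HSV value channel. HSV value (not grayscale luminance) is used
because the measures are defined in HSV space throughout; hue is reported
on [0,1) and achromatic pixels carry hue 0 and stay in the mean, matching
common image-library behaviour.

## Ground truth and BOLD forward model

A `ground_truth` object holds named voxel regions, a region × condition
amplitude table, noise and drift levels, and the simulated HRF. The forward
model is deliberately the same linear model the GLM assumes:

    y(t) = baseline + Σ_c amplitude_c · (boxcar_c ⊛ HRF)(t) + drift + ε

with white Gaussian noise and drift built from the same discrete-cosine
basis the high-pass filter spans. Consequently noiseless simulation
followed by the GLM recovers planted amplitudes to machine precision — a
deliberate closure property used by the tests, not a claim about real
neurovascular coupling. No scanner artifacts, no nonlinearity, no
spatiotemporal noise correlations are simulated; motion traces exist to
exercise FD scrubbing and do not perturb the signal.

Defaults are chosen to look like real task fMRI: baseline 100, noise SD 1.5
(temporal SNR ≈ 65), condition amplitudes 1–3 (i.e. 1–3% signal change),
multiplicative between-subject gain with SD 0.1, and drift coefficients of
about one signal unit on the slow cosine components. The default grid is
32 × 32 × 24 voxels at 1.5 mm with an ellipsoidal brain mask (≈ 10,400
voxels) — small enough that a 15-subject cohort runs in minutes on one CPU,
large enough for searchlights and cluster inference to behave
realistically.

The default layout plants four sources:

* `visual` — responds equally to all six conditions; drives the
  all > baseline localizer.
* `body_region` / `face_region` — small bilateral regions preferring bodies
  (respectively faces) over the other category and objects, with scrambled
  lowest. These are the fROI targets.
* `animate_patch` — all conditions respond equally on average, but the four
  animate conditions share a per-voxel gain field (pattern SD 0.5 of the
  mean amplitude, drawn per subject), while objects and scrambled have no
  reliable pattern. This is the RSA animacy target: mean similarity among
  animate trials is high where the shared field lives, object-pair
  similarity is not.

Two geometric rules matter. First, regions are disjoint. Second, the
pattern patch is placed so that its gap to every other source exceeds the
searchlight diameter: searchlight similarity spreads by about one radius
beyond a source's edge, and univariate region *boundaries* themselves
produce genuine similarity clusters (every trial shares the boundary
profile, scaled by its amplitude). Sources closer than the smear bridge
into a single cluster and can no longer be attributed separately. This
boundary-profile effect is a real property of searchlight RSA, not an
artifact of the simulation, and is why the group maps for the
faces/bodies/animate vs objects comparisons also show clusters over the
univariate regions.

## Motion and scrubbing

Motion traces are smoothed cumulative-sum wander (translation increment SD
0.02 mm; rotations 1/50 of that in radians) plus optional spikes applied as
sustained steps of the x-translation — the head settles in a new position —
so each spike yields exactly one FD exceedance. FD is the Power-style sum
of absolute parameter differences, rotations converted to arc length at a
head radius of 50 mm for simulated humans and 30 mm for the smaller dog
head. Scans with FD > 0.5 mm each get a one-hot nuisance regressor
(scrubbing). The default spike rate (2% of scans, magnitudes 0.7–1.5 mm)
produces scrub fractions of a few percent, between the ≈ 1% typical of
cooperative humans and the ≈ 8% of awake dogs.

## Haemodynamic response functions

Both presets are peak-normalised differences of gamma densities sampled at
dt: the human preset uses the canonical parameters (peak delay 6 s,
undershoot delay 16 s, dispersions 1 s, undershoot ratio 1/6, 32-s kernel;
sampled peak at 5.0 s). The dog preset keeps the family and moves the peak
delay to 3.5 s (undershoot 13.5 s), placing the sampled peak 2.5 s earlier
— the midpoint of the 2–3 s advance reported for dogs. The exact fitted
canine parameters vary across labs, so they are an exposed configuration,
not a fixed constant.

## First-level GLMs

Design matrices contain one boxcar-convolved column per condition,
`floor(2·N·TR/cutoff)` discrete-cosine drift columns for the 128-s
high-pass, the six (demeaned) realignment parameters, the scrubbing
indicators, and an intercept. Estimation is plain voxel-wise OLS — no AR(1)
prewhitening, consistent with the white noise the generator produces; on
real data the standard errors (not the betas) would be optimistic.
Rank-deficient designs fall back to the pseudoinverse with a warning.
All-NaN voxel series are dropped from the mask with a count.

Single-block ("least-squares-single") GLMs fit each block with one target
regressor and one combined all-other-blocks regressor plus the shared
nuisance set, per run. With unequal condition amplitudes the HRF overlap
between neighbouring blocks biases single-block betas slightly (the tests
bound the deviation from the condition-level fit at 0.25 signal units on
noiseless data); this is inherent to the single-trial decomposition, not an
implementation artifact.

## Functional ROIs

Search spaces are all candidate anatomical masks ("gyri") that intersect a
significant cluster of the group-level all > baseline localizer from run 1.
Within a search space, an fROI is defined per subject and hemisphere by
(1) keeping voxels with a strictly positive preference contrast and
(2) keeping the top-`p`% of them by the target contrast, with
`k = max(1, ceiling(p/100 · N_pref))` — the ceiling-with-floor rule
guarantees nonempty fROIs in small spaces. Hemispheres are assigned by the
sign of the world x coordinate (exact midline → left). Extraction uses the
unweighted bilateral mean of left-out-run contrasts; defining and
extracting on the same run is rejected by a provenance check on the maps'
run tags. Planned pairwise comparisons answering one question across fROIs
(e.g. "does every body fROI prefer bodies?") are FDR-corrected together as
one family.

The validation analyses mirror the main ones: the stability sweep re-runs
define-and-extract over the grid {1, 5, 10, …, 100}%, and the resampling
control repeats the group ANOVA over subsamples drawn without replacement.

## Searchlight RSA

Sphere offsets are all integer voxel offsets whose mm distance to the
centre is within the radius. The dog preset (r = 4 mm, 1.5 mm grid) gives
81 voxels with either boundary rule; the human preset is documented as
r = 8 mm on a 2 mm grid with an *exclusive* boundary, which gives 251 — the
only convention under which both published neighbourhood sizes arise, since
a ≤-boundary on 1.5 mm (the resliced resolution) matches neither. Both
rules are implemented and the choice is explicit in `searchlight_spec()`.

Valid centres are in-mask voxels with at least `min_gray_voxels` in-mask
sphere voxels (15 dog / 30 human). Per centre, all unordered pairs of
distinct trials in a set are Pearson-correlated over the in-mask sphere
voxels; correlations are Fisher-z transformed with |r| capped at 1 − 1e-6
(identical patterns otherwise give infinite z) and averaged. Self-pairs are
excluded; pairs spanning the two runs are included; pooled sets include
cross-species pairs by default, with `within_species_pairs_only` preserving
the alternative reading. Zero-variance trial patterns inside a sphere have
their pairs skipped with a count; a centre with no usable pair is NaN.

## Permutation inference

Group tests are sign-flip permutation tests on subject difference maps
(one-sample tests use the maps themselves). When `2^n ≤ n_perm` the flip
set is enumerated exhaustively (identity included), so corrected p-values
are exact multiples of `2^-n`; otherwise `n_perm` random flips are drawn
and `p = (1 + #{null ≥ obs}) / (1 + n_perm)`, which is never zero. The
cluster-defining threshold is the positive tail of the two-sided t quantile
at the configured p (0.005 dog / 0.001 human presets) with n − 1 degrees of
freedom; clusters use 18-connectivity (faces + edges), the common
convention in SPM-family software. Degenerate zero-variance voxels get
t = 0 with a warning. No variance smoothing is applied.

## Problem sizes used by the test suite

The suite exercises every stage at sizes chosen to make the statistics
meaningful on one CPU: oracle-equivalence checks on grids up to 10×10×6
with all 36 trials; permutation FWER calibration over 200 null cohorts of
12 subjects (12×12×8 grid, 500 permutations each, band 0.02–0.09 around the
nominal 0.05); resampling type-I calibration over 12 independent null
cohorts × 80 subsamples; and an end-to-end recovery run with the default
15-subject dog preset (1000 permutations, RSA comparison c). The pipeline
replay test uses a reduced 20×20×16 grid purely to assert byte-identical
manifests.

## What passing tests do and do not show

The generator produces linear, white-noise, drift-contaminated data with
block-level reliability and no spatial autocorrelation beyond the planted
structure. Passing recovery and calibration tests therefore shows the
*pipeline logic* is correct (no split-half leakage, correct selection
arithmetic, calibrated nulls, correctly assembled similarity sets) — it
does not validate assumptions that real data would stress: autocorrelated
and heavy-tailed noise, imperfect HRF models, registration error,
physiological confounds, or similarity driven by low-level image
properties. The package's claims end at the method; nothing here is
evidence about actual dog or human neuroanatomy.

## Known limitations

* OLS without prewhitening; standard errors on autocorrelated data are
  anti-conservative (group-level permutation inference is unaffected under
  subject exchangeability).
* No sphericity correction in the 3-level repeated-measures ANOVA (the
  2-level and 2×2 cases are sphericity-free by construction).
* Single-block betas are mildly biased under unequal amplitudes (see
  above).
* The stimulus generator controls extent, hue, saturation and contrast but
  does not emulate natural image statistics (spatial frequency spectra,
  clutter).
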