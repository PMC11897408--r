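---
title: "Quantifying mitotic chromatin decondensation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitotic chromatin decondensation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decondenseR)
```

## The measurement problem

During mitotic exit, the compact chromatid masses of anaphase relax into
diffuse interphase chromatin. Two observable signatures of this
decondensation drive everything in this package:

1. **Boundary smoothing.** A condensed cluster of mitotic chromosomes has a
   ragged outline; a decondensed chromatin mass has a smooth, nearly convex
   one. On fixed, DAPI-stained in-vitro substrates this can be scored per
   object from a single image.
2. **Area growth.** In live H2B-labelled cells, the summed area of the two
   daughter chromatin masses grows steadily from anaphase onset; slowed
   decondensation shows up as a flatter area curve and a longer telophase.

The package implements both readouts end to end — segmentation, the
border-smoothness statistic, anaphase-aligned area curves, phase dwell
times, perichromatin marker intensities and cytoplasmic foci — together with
a synthetic-data generator that produces images with exactly known ground
truth, so every stage is testable without microscope data.

## The border-smoothness score

For a segmented chromatin mask $M$, a *soft-border* version $S(M)$ is
computed with a binary median filter (majority vote in a $k \times k$
window, reflect padding), and the score is the intersection-over-union

$$ s \;=\; \frac{|M \cap S(M)|}{|M \cup S(M)|} \in [0, 1]. $$

A smooth mass is nearly a fixed point of the median filter, so $s \to 1$;
boundary roughness finer than the kernel scale is erased by the filter and
lowers $s$. The score is exactly 1 when softening leaves the mask unchanged,
and it is invariant under translation and 90-degree rotation because the
filter window is square and symmetric.

**Kernel size.** The soft-border kernel is the one tunable parameter that
matters (`soft_kernel_px`, default 15). It must sit between two scales: much
larger than the roughness wavelength to be erased, and much smaller than the
object radius so the bulk survives. The default 15 px suits objects of
roughly 50 px radius (guidance: about 0.3 of the radius); a perfect digital
disk of radius 50 then scores 0.9908. On rough masks the score is
non-increasing in the kernel, so comparisons are only meaningful at a fixed
kernel — the package stamps the configuration hash into every report for
this reason.

**Per-object scoring.** Scores are computed per connected chromatin object,
not per image, because the natural experimental unit is the chromatin
substrate; hierarchical summaries then aggregate objects within experiments.

## Segmentation recipes

Two fixed recipes are provided rather than one configurable soup, mirroring
how fixed-sample and live-cell data are processed differently in practice:

* `segment_invitro()`: median denoise (default 3 px — the smallest
  effective window; the kernel is configurable because no single value
  suits all cameras), conversion to 8-bit (min to 0, max to 255), Otsu
  threshold, hole filling.
* `segment_livecell()`: Gaussian blur with sigma 1.5 px, Otsu threshold,
  hole filling. No 8-bit conversion by default.

Otsu's threshold is computed by an exhaustive sweep of the 256-bin
histogram for the threshold maximizing between-class variance, with ties
broken toward the smallest maximizing bin; a constant image has no
threshold and raises a degenerate-input error unless the caller opts into
an empty mask. Fiji-style "Default" (IsoData-like) thresholding used in
some intensity workflows is deliberately mapped onto Otsu here: one
threshold family keeps the whole pipeline oracle-testable, at the cost of a
small systematic difference from IsoData on skewed histograms.

Conventions used everywhere: pixel-center-in-region rasterization, 0-based
row/column coordinates with the origin at the top left, 8-connected
foreground with 4-connected background (the standard dual, which avoids
topological paradoxes in hole filling), and reflect padding for all finite
filter windows (so constant images are fixed points and no dark rim biases
the threshold).

## Time-course analysis

Per-frame masks are reduced to at most the two largest objects, linked by
nearest centroids (with the two-permutation assignment minimizing summed
displacement when two objects persist). **Anaphase onset** (t = 0) is the
first frame at which two daughter masses are segmentable — operationalized
as: exactly two objects, each at least `anaphase_min_daughter_frac`
(default 0.2) of the preceding single-mass area, persisting for two
consecutive frames. The persistence guard exists because segmentation noise
can transiently split a mass; one spurious frame must not anchor the whole
curve. Trajectories with no qualifying split are discarded and the reason
logged, making the discard step auditable.

Normalized area curves divide the summed daughter area by its value at
onset, so every curve passes through exactly 1 at t = 0; frames before
onset appear at negative times with the same denominator. The per-minute
expansion rate is recovered as the zero-intercept least-squares slope of
(normalized area − 1) against time.

**Phase classification** uses explicit size rules relative to an interphase
reference nuclear area: a single mass at or above `telophase_exit_frac`
(default 0.8) of the reference is interphase; a single mass below
`metaphase_area_frac` (default 0.4) is metaphase; single masses in between
are prophase. Two-object frames are anaphase for the first two frames after
onset, then telophase until a daughter reaches the exit fraction. These
cut-offs are deliberately simple and fully exposed: the goal is a
reproducible, tunable rule, not a learned classifier. When no reference
area is supplied, a never-splitting trajectory uses the median
single-object area of its first five frames; a mitotic trajectory (which
typically starts in the last metaphase, where the interphase scale is not
observable) takes the pre-split mass as a metaphase plate occupying 35% of
the interphase nuclear footprint — the same convention the synthetic
generator uses, and a number a user with real data should override.

Dwell times are contiguous run lengths times the frame interval; telophase
dwell is the headline readout of delayed decondensation.

## Intensity and foci quantification

Marker intensity on chromatin is the mean over the chromatin mask;
background is the mean inside a circular ROI (default radius 10 px)
rejection-sampled uniformly over the admissible region — centres whose
whole disk lies in the cytoplasm, i.e. inside the cell but beyond a 4-px
dilation of the chromatin mask so a perichromatin rim never contaminates
the background. The sampler is seeded and reproducible, and its centre
distribution is uniform over the admissible region (the rejection proposal
is uniform over the frame). Corrected intensity is on-mask mean minus
background mean; negative values are allowed and flagged rather than
clipped.

Line scans take 200 samples at equal spacing between two endpoints,
inclusive, with bilinear interpolation; the sample count and interpolation
are stated because neither is standardized across imaging software.

Foci detection is an explicit algorithmic surrogate for by-eye scoring of
cytoplasmic granules: the cytoplasm is thresholded at 3 times its median
intensity, 8-connected components of at least 4 px² are foci, and a cell is
positive for "big" foci when any focus reaches 25 px² at that intensity
fold. All three numbers are parameters reported in the output — visual
scoring has no documented thresholds, so reproducibility is preferred over
fidelity to an undocumented judgment.

## Statistics

The testing workflow is gate-based: both samples are tested for normality
with Shapiro-Wilk at alpha = 0.05; if both pass, a two-tailed Welch t test
is used, otherwise a two-tailed Mann-Whitney U test. The gate — not the W
statistic — is the tested behaviour, and the gate decision is always
reported. The Mann-Whitney p-value is exact (full enumeration over group
assignments of pooled mid-ranks, so ties are handled exactly) whenever the
pooled sample size is at most 12, and a normal approximation with tie and
continuity corrections otherwise. Fisher's exact test uses the
probability-mass two-sided rule. Counts of cells per condition are compared
with Fisher; no multiple-testing correction is applied, matching
per-comparison reporting. Hierarchical summaries emit per-experiment means
plus an overall mean and s.e.m. on a *declared* basis (across experiments
or across units) — published figures are often ambiguous about which basis
backs a printed ±, so both are available and the basis is recorded.

## The synthetic generator

The generator emulates three kinds of data, each with exact ground truth:

* **Chromatin masses** with boundary
  $r(\theta) = R\,(1 + a \sum_{j=1}^{m} c_j \cos(j\theta + \phi_j))$, with
  seeded coefficients normalized so $\sum_j |c_j| = 1$. The amplitude $a$ is
  then the maximum fractional radial excursion — a single interpretable
  "condensation" knob ($a = 0$ is a perfect disk). Intensity is rendered,
  blurred (a point-spread surrogate), and Gaussian noise is added after the
  blur and clipped at zero, mimicking the usual noise-on-PSF ordering
  without modelling either physically.
* **Mitotic-exit time-lapses**: one metaphase mass until the onset frame,
  then two daughters (mirror images of a single boundary draw) separating
  at constant speed while the true summed area follows
  $A(t) = A_0 (1 + k t)$. The generator guarantees daughters never touch or
  leave the frame (it errors rather than silently clipping), so per-frame
  truth stays exact.
* **Two-channel cells**: a chromatin channel plus a marker channel carrying
  a perichromatin rim band (dilation of the mask minus the mask), uniform
  cytoplasm inside a cell disk, and optional bright cytoplasmic foci placed
  by rejection sampling with pairwise separation of at least four focus
  radii.

Default study conditions: 3-minute frame intervals; 0.11 µm/px (a common
60x spinning-disk sampling — figure pixel sizes are rarely published, so
this is a convention, not a measured value); intensities on a [0, 1] scale
with foreground 0.85 over background 0.08; expansion rates in the
0.02–0.125 /min range, which reproduce the qualitative shape of published
normalized-area curves; signal-to-noise 5 (noise sd = contrast / 5) where
noise robustness is exercised. The condensed-cluster fixture uses a = 0.35
with 12 harmonics against a = 0.02 for decondensed masses.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: harmonic boundaries are band-limited, so they
never reach the fine, chromosome-scale raggedness of real condensed
clusters (synthetic condensed masses score around 0.96 at the default
kernel rather than the much lower scores seen on real clusters — the
direction and detectability of the contrast are preserved, the dynamic
range is not); noise is additive Gaussian, not Poisson shot noise; there is
no photobleaching, focus drift, cell crowding or debris; daughters never
touch, whereas real telophase masses can; and the marker channel has
piecewise-constant compartments rather than graded localization. Results on
real microscopy data therefore need the usual visual sanity checks,
especially of segmentation masks.

## Numerical choices and degenerate inputs

* Otsu ties break toward the smallest maximizing threshold; constant images
  raise errors rather than guessing.
* Binary medians with odd kernels cannot tie, so the majority rule is
  unambiguous.
* An empty mask has no smoothness score (error); a non-empty mask whose
  softened version is empty scores 0 with a warning.
* Welch's t with two zero-variance samples returns t = 0, p = 1 when means
  are equal and errors when they differ (the statistic is undefined).
* s.e.m. over a single experiment (or unit) is reported as 0 with an
  explicit single-basis flag rather than NA, so downstream tables stay
  numeric; n is always reported alongside.
* All randomness (synthetic draws, background ROIs) flows from explicit
  seeds; identical configuration and seed reproduce byte-identical CSV and
  JSON outputs.

## Problem sizes used in the checks

The packaged tests and the acceptance script run entirely on synthetic
cohorts sized to exercise the statistics without waste: 30 masses per
roughness amplitude for the monotonicity check, two experiments of 25
objects per condition for the end-to-end contrast, 50 time-lapses for
onset detection, 20-cell cohorts for dwell and expansion-rate recovery,
and 1000 simulated null pairs per distribution for the type-I calibration
of the gated test.

## Known limitations

* Tracking handles at most two chromatin objects per frame — single-cell
  crops are assumed, as produced by typical trajectory extraction; fields
  with bystander cells must be cropped upstream.
* No watershed splitting: touching daughter masses merge back into one
  object and postpone detected onset.
* The Fiji "Default"/IsoData vs Otsu substitution above.
* Phase rules assume the standard mitotic progression; exotic phenotypes
  (multipolar divisions, mitotic slippage) are out of scope.
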