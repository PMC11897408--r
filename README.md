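# decondenseR

Quantification of mitotic chromatin decondensation from fluorescence
microscopy, for cell biologists measuring mitotic exit: how fast and how
completely condensed mitotic chromosomes relax back into interphase
chromatin.

The package implements two headline readouts plus their supporting
measurements:

* **Border smoothness** (fixed in-vitro chromatin substrates). A segmented
  chromatin mask *M* is compared with a soft-border version *S(M)* obtained
  by a binary median filter; the score is the intersection-over-union

  &nbsp;&nbsp;&nbsp;&nbsp;*s* = |M ∩ S(M)| / |M ∪ S(M)| ∈ [0, 1].

  Smooth decondensed masses are near fixed points of the softening
  (*s* ≈ 1); ragged condensed clusters score lower.
* **Anaphase-aligned chromatin-area time courses** (live H2B time-lapses).
  Frames are segmented (Gaussian blur σ = 1.5 px, Otsu threshold, hole
  filling), the two daughter masses are tracked, t = 0 is set to the first
  frame where two daughters are segmentable, and the summed area is
  normalized to that frame. The per-minute expansion rate *k* of
  A(t) = A₀(1 + k·t) is recovered by least squares, mitotic phases are
  classified from mass sizes, and telophase dwell time is reported.
* **Perichromatin marker intensities** (background-corrected means over the
  chromatin mask, with a seeded random cytoplasmic ROI), 200-sample
  bilinear line scans, and cytoplasmic foci detection.
* **Statistics** matching common practice in this field: Shapiro-Wilk
  normality gate at α = 0.05 choosing between a two-tailed Welch *t* test
  and a two-tailed Mann-Whitney *U* test (exact by enumeration at small n,
  ties handled), Fisher's exact test for per-cell counts, and hierarchical
  experiment-level summaries (per-experiment means, overall mean ± s.e.m.
  on a declared basis).

A synthetic-data generator produces chromatin masses with controllable
boundary roughness, mitotic-exit time-lapses, and two-channel cells with a
perichromatin rim and cytoplasmic foci — all with exact ground truth — so
the entire pipeline is testable with no microscope data. See the methods
vignette (`vignettes/decondensation-quantification.Rmd`) for the model,
parameter defaults and design rationale.

## Worked example

Score a decondensed versus a condensed synthetic chromatin substrate:

```r
library(decondenseR)

g_dec <- make_chromatin_mass(mass_params(roughness_amplitude = 0.02,
                                         n_harmonics = 12, radius_px = 45,
                                         noise_sd = 0.02, seed = 1))
g_con <- make_chromatin_mass(mass_params(roughness_amplitude = 0.35,
                                         n_harmonics = 12, radius_px = 45,
                                         noise_sd = 0.02, seed = 1))
score_image(g_dec$frame, image_id = "decondensed")
#>         image object_id         s intersection_px union_px area_px2
#> 1 decondensed         1 0.9896389            6304     6370     6370
score_image(g_con$frame, image_id = "condensed")
#>       image object_id         s intersection_px union_px area_px2
#> 1 condensed         1 0.9552789            6216     6507     6400
```

The rough (condensed) mass loses boundary detail to the softening filter
and scores lower (0.955 vs 0.990); over cohorts this contrast is what the
in-vitro pipeline tests.

Analyze a synthetic mitotic-exit time-lapse:

```r
tl <- make_decondensation_timelapse(timelapse_params(expansion_rate = 0.05,
                                                     seed = 4))
cfg <- pipeline_config(segmentation = segmentation_config(to_8bit = FALSE))
res <- analyze_trajectory(tl$lapse, cfg, "cell01")
res$onset
#> [1] 8                      # detected first two-daughter frame (truth: 8)
head(res$curve[res$curve$time_min >= 0, ], 4)
#>    cell_id time_min normalized_area
#> 9   cell01        0        1.000000
#> 10  cell01        3        1.159705
#> 11  cell01        6        1.307125
#> 12  cell01        9        1.454545
fit_expansion_rate(res$curve)
#> [1] 0.0495188              # true k = 0.05 / min
res$dwell$minutes
#> interphase   prophase  metaphase   anaphase  telophase
#>          0          0         24          6         30
```

The curve is anchored at exactly 1 at anaphase onset, the fitted expansion
rate recovers the generator's truth within 1%, and dwell times are run
lengths times the 3-minute frame interval.

Hierarchical summaries report per-experiment means (the "triangles" of a
superplot) with the s.e.m. basis made explicit:

```r
summarize_hierarchical(c(1, 2, 3, 4, 5, 6), rep(c("e1", "e2"), each = 3))
#> <hierarchical_summary> overall 3.5 +/- 1.5 s.e.m. (basis: experiments; 2 experiments, 6 units)
#>   experiment means: e1=2, e2=5
```

`run_invitro_pipeline()` and `run_livecell_pipeline()` chain these stages
over whole cohorts and write `scores.csv` / `curves.csv`, `phases.csv`,
`dwell_min.csv` plus JSON reports stamped with the package version and a
configuration hash; reruns with the same configuration and seed are
byte-identical. A thin command-line wrapper lives at
`inst/cli/decondenseq.R` (`simulate`, `smoothness`, `run-invitro`,
`run-livecell`).

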