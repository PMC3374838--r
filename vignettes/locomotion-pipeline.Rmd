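---
title: "Quantifying C. elegans locomotion: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying C. elegans locomotion: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locotrack)
```

# The measurement problem

Crawling *C. elegans* on an agar plate are, under dark-field illumination,
bright blobs on a dark background. A plate camera sampling at 1 Hz over a
2-minute assay yields a stack of frames from which one wants, per animal:
the centroid path, the instantaneous speed, the acceleration, and summary
statistics that let populations (genotypes, feeding states, drug
pretreatments) be compared at matched speeds. Two features of worm
locomotion make this more than a bookkeeping exercise:

* **average speed and speed fluctuation are separate phenotypes.** A strain
  can crawl at a normal mean speed yet show abnormally large swings in
  speed (the phenotype of dopamine-deficient mutants), so the pipeline must
  quantify the within-track variability — the SD of a track's speed
  recordings, its CV, the RMS of its acceleration, and the duration and
  peak of individual acceleration events — separately from the mean.
* **fluctuation size covaries with average speed.** Faster animals
  fluctuate more even in wild type, so naive population comparisons
  confound the two. The standard correction, implemented here, bins tracks
  by average speed and compares genotypes within bins (two-way ANOVA:
  genotype + speed bin).

`locotrack` implements the full chain — synthetic data generation,
detection, tracking, kinematics, statistics — with each stage usable on its
own through plain TSV interchange files.

# The synthetic trajectory generator

No public video recordings accompany the assay this pipeline targets, so
the package ships a generator whose outputs have the statistical structure
the analysis assumes, and all tests run against its known ground truth.

## Speed process

Speed is modelled as a mean-reverting diffusion reflected at zero:

$$dv = \theta(\mu - v)\,dt + \sigma\,dW, \qquad v \ge 0 .$$

The three parameters map one-to-one onto the phenotype axes the analysis
measures:

| parameter | units | meaning | wild-type default |
|---|---|---|---|
| `mu_speed` | mm/s | long-run mean speed | 0.15 |
| `theta` | 1/s | mean-reversion rate (1/correlation time) | 0.2 |
| `sigma` | mm s^-3/2 | fluctuation drive | 0.023 |
| `turn_sd` | rad/step | heading random-walk scale | 0.5 |

The stationary SD of the unreflected process is $\sigma/\sqrt{2\theta}$
(~0.036 mm/s at the wild-type default), so mean and fluctuation size are
independently tunable — exactly the dissociation the analysis must be able
to resolve. Observed crawling speeds on food span roughly 0–0.3 mm/s,
which anchors `mu_speed` and the fluctuation scale; `theta = 0.2`/s gives
a ~5 s speed correlation time, so successive 1 Hz samples are correlated
the way smoothed worm speed recordings are. Strain presets
(`genotype_preset()`) are phenomenological: they reproduce *orderings*
(dopamine-deficient sigma twice wild type; mild hyperactivity; a slowed
variant with mutant-sized fluctuations), not any published strain's exact
numbers, because no quantitative model links dopamine level to
acceleration control.

Numerical choices: the transition is sampled from the exact Gaussian
conditional law of the Ornstein–Uhlenbeck process rather than an Euler
step, because the Euler scheme inflates the stationary variance by a
factor $1/(1-\theta\,\Delta t/2)$ — a ~2.6 % SD bias at
$\theta\,\Delta t = 0.1$ that would contaminate parameter-recovery checks.
Reflection at zero is the absolute value after each step, the simplest
scheme preserving nonnegativity; it perturbs the mean and SD only when the
boundary is visited, i.e. when `mu_speed` is within about two stationary
SDs of zero. An internal sub-stepping option (`n_substeps`) integrates the
process finer than the camera rate and averages within each observation
interval; the default is 1 because the exact transition makes refinement
unnecessary for distributional accuracy.

## Trajectories, arena, dropout

Headings perform a Gaussian random walk (`turn_sd` per step); each
per-frame displacement has magnitude `speed * dt` before boundary
handling; at the arena walls the position is mirrored and the heading
flipped, which keeps 2-minute tracks in frame as a physical plate does.
Note one consequence used by the tests: away from walls, measured
centroid displacement equals true speed exactly, so detection + kinematics
can be validated against ground truth to machine precision.

Per-frame, per-animal detection dropout (`dropout_prob`) stands in for
*every* fragmentation mechanism of real recordings — missed detections,
animals touching and merging into one blob, edge excursions. The default
0.33 was set so that, with the tracker's 2-frame gap bridging and 30 s
minimum-duration filter, the mean filtered track length is ~53 s in a
120 s assay, the fragmentation level typical of multi-worm plate
recordings. What the generator deliberately does not model: worm body
posture (the pipeline tracks centroids only), bacterial-lawn geometry, and
any pharmacokinetics of dopamine pretreatment (a preset, nothing more).
Passing tests therefore certify the *computational* chain, not robustness
to posture-induced centroid wobble or to dense-plate occlusion patterns.

# Detection

`detect_centroids()` thresholds the frame at a fixed global level
(synthetic frames have controlled contrast, so adaptive thresholding would
add a degree of freedom without a benefit), labels 8-connected components
(robust to the thin diagonal joins elongated blobs produce), discards
components below `min_area`, and reports each component's
intensity-weighted centre of mass — sub-pixel, which matters because at
0.01 mm/px a 0.2 px error is 2 µm, well below per-frame displacements.
Output is sorted by (y, x) so results are independent of component
discovery order. Merged blobs are detected as one object by design;
disambiguation is left to the tracker's termination logic.

# Tracking

Per frame, open track heads are matched to detections by
minimum-total-distance one-to-one assignment (Hungarian algorithm on the
gated distance matrix, solved exactly within connected components of the
admissibility graph). This is deterministic and order-independent, unlike
greedy nearest-neighbour, and coincides with it when animals are far
apart. Ties are broken toward lower (track, detection) indices via a
sub-resolution cost perturbation.

Gating: a head may claim a detection within `max_disp` (default 0.5 mm at
1 Hz, comfortably above the ~0.3 mm/s maximum crawling speed). A head
undetected for $g$ frames keeps a claim radius of $(g+1) \cdot$
`max_disp`: with a fixed radius, gap bridging selectively fails for fast
animals (three frames of motion at 0.2 mm/s exceeds 0.5 mm), which
fragments hyperactive-genotype tracks and biases the duration-filtered
population toward slow episodes — a genotype-dependent selection artifact
the time-scaled gate removes. Tracks unmatched for more than `max_gap`
frames (default 2) are closed; unclaimed detections seed new tracks;
fragments of fewer than two observations are reported separately so that
detection counts are conserved. When two animals merge into one blob, the
losing track times out and terminates — fragmentation instead of guessed
identities, consistent with short mean track lengths in crowded assays.

# Kinematics

Raw speed is path distance per interval, $|p_{i+1}-p_i|/\Delta t$. The
reported speed recording is a 5-sample (5 s at 1 Hz) sliding-window mean,
which suppresses centroid-localization noise; only full windows are
emitted (trailing indexing, times attached at window centres for plotting
only), so every smoothed sample has the same variance — shrinking edge
windows would not. Bridged 1–2-frame gaps are linearly interpolated first
to keep $\Delta t$ uniform; interpolated rows are flagged. Acceleration is
the first difference of the smoothed speed over $\Delta t$; computing it
from the raw speed instead would multiply localization noise into every
event statistic, and the smoothed series is the quantity the assay calls
a "speed recording".

An acceleration event is a maximal run of same-sign acceleration — the
time between the acceleration leaving zero and returning to it. Exact
zeros belong to no event (the literal reading of the definition); because
floating-point accelerations are almost never exactly zero on real or
simulated data, this convention only matters for constructed inputs, and
it is what the brute-force enumeration oracle in the test suite encodes
too. Per track, the pipeline reports: mean and sample SD (n−1 denominator
— tracks are finite samples; recorded explicitly because either convention
is defensible) of the smoothed speed, their ratio (CV, undefined — not
infinite — for a zero-mean track), RMS acceleration, mean event duration,
and mean signed peaks of acceleration and deceleration events separately;
event fields of a track with no events are `NA`, never zero.

Only tracks spanning at least 30 s enter population statistics
(`filter_tracks()`): shorter tracks make the within-track SD itself too
noisy to average.

# Population statistics

* `population_average_speed()`: the mean of all pooled smoothed speed
  samples — long tracks weigh more, by definition of "fraction of time".
* `speed_histogram()`: pooled samples in half-open bins $[kw,(k+1)w)$
  (default width 0.006 mm/s), normalized to fractions; weighting is by
  sample, not by track, to represent time spent at each speed.
* `bin_tracks_by_avg_speed()`: tracks assigned to bins by
  `floor(avg_speed / width)` (default 0.03 mm/s); per-bin mean and SEM of
  any per-track statistic, each track one independent measurement; a
  single-track bin has an undefined (`NA`) SEM.
* `two_way_anova()`: `value ~ genotype + bin`, least squares on the
  unbalanced design, Type-II sums of squares (via `car::Anova`), reporting
  the genotype main effect. No interaction term by default — the question
  is a genotype offset across the speed range — though `interaction =
  TRUE` is available; bins with fewer than two tracks are dropped because
  they contribute no within-cell variance. No multiple-testing correction
  is applied anywhere; p-values are reported raw.
* `t_test_tracks()`: Student's pooled-variance t-test (Welch behind a
  flag); the degenerate zero-variance-both-groups case returns p = 1 on
  equal means rather than erroring.

Calibration of these tests is checked by simulation at the
statistic level: null replicates draw per-track values from a normal
distribution within a genotype × bin design, which isolates the
implementation's type-I error from the (separate) question of F-test
robustness to the skewness of real per-track SD distributions.

# Problem sizes and determinism

Every stochastic function takes an explicit seed and restores the caller's
RNG state; `run_pipeline()` derives all stage randomness from the single
config seed and writes a manifest with MD5 checksums, so a config file
fully reproduces a run byte-for-byte. The validation suite runs at desk
scale by design: oracle comparisons at 500–1000 random instances,
identity-recovery at 20 animals × 120 s over many seeds, population
contrasts at 100–200 tracks per genotype — sizes chosen to give binomial
or Monte-Carlo error well inside the asserted tolerances while keeping a
full run in minutes on one core.

# Known limitations

* Centroid-only: posture, body bends, reversals and omega turns are out of
  scope, and the generator cannot emulate posture-induced centroid wobble.
* Merged blobs are unresolved by construction; in dense arenas the
  pipeline trades coverage (shorter tracks) for identity purity.
* The interpolation of bridged gaps measures chord rather than path
  distance across the gap, biasing speed slightly downward on strongly
  curved paths.
* The reflected OU speed process is phenomenological; its presets encode
  orderings between conditions, not measured parameters of any strain.
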