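# locotrack

Automated quantification of *C. elegans* crawling behaviour from
dark-field image stacks or per-frame centroid tables, for researchers
phenotyping locomotion across genotypes, feeding states or drug
pretreatments.

The pipeline mirrors the standard plate-camera assay: frames at 1 Hz for
2 minutes, worms as bright blobs on a dark background. Per frame, blob
centroids are the intensity-weighted centres of mass of 8-connected
supra-threshold components. Centroids are assembled into per-animal tracks
by gated minimum-cost bipartite assignment (Hungarian algorithm), with
bridging of short detection gaps. Per track, speed is path distance per
interval smoothed over a 5-sample (5 s) sliding window,

v̄ᵢ = (1/5) Σₖ₌ᵢ..ᵢ₊₄ |p(k+1) − p(k)| / Δt ,

acceleration is the first difference aᵢ = (v̄ᵢ₊₁ − v̄ᵢ)/Δt, and
acceleration *events* are maximal same-sign runs of aᵢ delimited by zero
crossings, each with a duration and a signed peak. Tracks spanning ≥ 30 s
yield per-track statistics — mean speed, intra-track speed SD and CV, RMS
acceleration, mean event duration, mean peak acceleration/deceleration —
which are compared across populations by binning tracks on average speed
(half-open bins, width 0.03 mm/s) and testing the genotype effect with a
Type-II two-way ANOVA (`value ~ genotype + speed_bin`) plus Student's
t-tests within bins. The separation matters because speed fluctuation
covaries with average speed: binning compares genotypes at matched speeds.

Because no public recordings accompany this assay, the package includes a
ground-truth generator: speed follows a mean-reverting diffusion reflected
at zero, dv = θ(μ − v)dt + σ dW (stationary SD σ/√(2θ)), headings a
Gaussian random walk, with arena reflection and per-frame detection
dropout. Mean speed (μ) and fluctuation magnitude (σ, θ) are independently
tunable — the two phenotype axes the analysis must resolve.

## Worked example

Simulate a mixed plate of wild-type-like and dopamine-deficient-like
animals, run the full pipeline, and test for a genotype effect on speed
fluctuations:

```r
library(locotrack)

cfg <- pipeline_config(n_animals = 40L, seed = 1L)
m   <- run_pipeline(cfg, out_dir = "demo_out")

m$n_tracks_linked     # 139 raw track fragments
m$n_tracks_filtered   # 53 tracks span >= 30 s
m$mean_track_length_s # 59.5 s

round(tapply(m$stats$avg_speed, m$stats$genotype, mean), 3)
#> dopamine_deficient           wildtype
#>              0.170              0.150
round(tapply(m$stats$speed_sd, m$stats$genotype, mean), 4)
#> dopamine_deficient           wildtype
#>             0.0536             0.0319

m$anova
#> Two-way ANOVA (Type II), n = 51 tracks
#>      term         F df df_resid            p
#>  genotype 13.944443  1       46 0.0005176491
#>       bin  2.365688  3       46 0.0831817783
```

The mutant-like population crawls slightly faster on average (0.170 vs
0.150 mm/s) but, more importantly, shows ~1.7× the within-track speed SD;
the ANOVA confirms the fluctuation difference is a genotype effect and not
explained by the speed difference (p ≈ 5e-4 after conditioning on speed
bin). `m$binned` holds the per-bin means ± SEM behind that comparison, and
every intermediate (truth, detections, tracks, per-track stats, histogram,
binned curves, a checksummed manifest) is written as TSV/JSON under
`demo_out/`.

A thin CLI wrapping the same functions lives at `inst/cli/locotrack.R`
(`simulate | detect | track | stats | compare | pipeline`), e.g.

```sh
Rscript inst/cli/locotrack.R pipeline \
  --config inst/extdata/example_config.yaml --out run1 --seed 3
```

See `vignettes/locomotion-pipeline.Rmd` for the generative model, every
tunable parameter with units and defaults, and the design decisions.

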