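Package: locotrack
Title: Multi-Animal Centroid Tracking and Locomotion Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated pipeline for quantifying Caenorhabditis elegans
    crawling behaviour from dark-field image stacks or centroid tables:
    per-frame blob detection by intensity-weighted centres of mass,
    frame-to-frame track assembly by gated minimum-cost assignment,
    sliding-window speed and acceleration kinematics, segmentation of
    acceleration events at zero crossings, and population statistics
    (speed histograms, speed-binned track summaries, two-way ANOVA and
    Student's t-tests). Includes a stochastic trajectory generator - a
    mean-reverting speed process with heading diffusion - so the whole
    pipeline is testable against known ground truth without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    rlang,
    withr,
    yaml,
    jsonlite,
    car,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
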