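Package: headtrunk
Title: Head-Trunk Coordination Analysis for Auditory Virtual-Reality Steering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates an acoustic virtual-reality arrow-steering task and
    synthetic cohorts of blind ("en-bloc"/"damping") and sighted
    ("articulated") head-trunk kinematics, computes jerk-based kinematic
    measures (trunk jerk RMS, prewhitened head-trunk cross-correlation
    peak) and spatial-performance measures (median signed final error,
    interquartile range), and runs the rank-based inferential layer: a
    2x2x2 mixed-design ANOVA on aligned-rank-transformed data, exact
    Mann-Whitney and Wilcoxon signed-rank post-hocs with Bonferroni
    correction, rank-biserial effect sizes with bootstrap confidence
    intervals, and a Monte-Carlo Lilliefors normality screen.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nortest,
    withr
Config/testthat/edition: 3
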