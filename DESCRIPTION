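Package: cmstrack
Title: Automated Video Scoring and Psychometrics for the Cervical
    Movement Sense Test
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores the clinical cervical movement sense test from video:
    a head-mounted laser dot is traced along a 1 mm zigzag line printed on
    an A3 board, the board is rectified to millimetre coordinates via its
    four corner fiducials, the dot is tracked frame by frame, and the
    outcome variables Acuity (percentage of trial time on the target
    line), Speed (mm/s), Time (s) and NormAcuity (Acuity/Time) are
    extracted per trial and pooled per subject. Includes the full
    psychometric battery used to evaluate the test (Shapiro-Wilk
    normality gating with Ln transform, three-group ANOVA with Bonferroni
    post-hoc, ROC discriminative analysis, Pearson correlation with neck
    disability, paired-t bias tests, ICC(2,k) with F-based confidence
    intervals, SEM and MDC), and synthetic-data generators: scripted
    ground-truth laser trajectories, rendered video frames, and simulated
    two-occasion three-group cohorts with known variance components.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
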