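Package: numadapt
Title: Frequency-Tagged EEG Analysis of Temporal Numerosity Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for EEG studies of temporal
    numerosity adaptation. Generates synthetic flash-sequence designs,
    behavioral numerosity estimates and multichannel EEG epochs with known
    ground truth; preprocesses epochs (linear-phase FIR band-pass, average
    reference, spherical-spline channel interpolation, peak-to-peak epoch
    rejection); quantifies steady-state visual evoked potentials by frequency
    tagging (selective averaging and single-sided FFT amplitude at the tagging
    bin); computes phase-based connectivity as inter-site phase clustering
    after surface-Laplacian filtering and narrowband Hilbert phase extraction;
    and provides the inferential statistics used in this literature: paired
    sign-flip permutation tests, Benjamini-Hochberg false discovery rate
    control, repeated-measures ANOVA with Greenhouse-Geisser correction,
    Bonferroni post-hoc comparisons, Spearman correlation, and the
    adaptation-percentage statistic.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
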