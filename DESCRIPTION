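Package: pulseshape
Title: Pulse Waveform Morphology and the Pulse Shape Index for
    Intracranial Pressure Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for morphological analysis of cardiac pulse waveforms in
    continuous intracranial-pressure (ICP) and noninvasive skull-expansion
    recordings. Provides multiscale trough detection for beat segmentation,
    normalization and resampling of single pulses, rule-based classification of
    the P1/P2/P3 peak configuration into four morphological classes with
    artifact screening, computation of the windowed Pulse Shape Index (PSI),
    and the accompanying method-agreement and nonparametric group-comparison
    statistics (Bland-Altman limits of agreement, Lin's concordance
    correlation, Kruskal-Wallis with Dunn post hoc tests, Wilcoxon signed-rank,
    Spearman correlation, and the Scheirer-Ray-Hare rank-based factorial
    analysis). A synthetic paired-signal cohort generator with ground-truth
    pulse onsets and class labels makes the whole pipeline testable without
    clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown,
    optparse
VignetteBuilder: knitr
Config/testthat/edition: 3
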