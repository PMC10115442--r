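Package: epiorient
Title: Spindle Orientation, Cortical Crescent and Clone Fate Analysis for
    Stratifying Epidermis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of oriented cell division in embryonic
    mouse epidermis. Provides perimeter linescan extraction and cortical
    polarity crescent metrics (maximum and integrated fluorescence
    intensity, cortical coverage, crescent position) from segmented
    mitotic cells; division-angle binning, empirical cumulative
    distributions and two-sample Kolmogorov-Smirnov comparisons;
    telophase-correction trajectory classification with Fisher and
    chi-square contingency tests; clonal lineage-tracing fate
    classification (symmetric and asymmetric divisions, delamination) and
    keratin-10 spinous thickness measurement; and a seeded synthetic-data
    generator that emulates the images and measurement tables these
    analyses consume, with ground truth attached for parameter-recovery
    testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    tiff,
    pracma,
    EBImage,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
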