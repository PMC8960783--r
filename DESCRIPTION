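Package: todrhythm
Title: Time-of-Death Transcriptome Rhythmicity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects 24 h rhythmic transcripts in postmortem expression data
    using each subject's time of death as a single circadian timepoint.
    Converts clock time of death to Zeitgeber time anchored at sunrise, fits
    fixed-period cosinor models by closed-form harmonic regression, assesses
    rhythmicity with permutation-based empirical p-values, classifies
    group differences in rhythmicity with a delta-R-squared permutation test,
    compares rhythmic gene sets with Fisher's exact test and rank-rank
    hypergeometric overlap, summarizes peak-hour structure with circular
    statistics and circular k-means, and builds phase-ordered heatmap and
    scatter report tables. Includes a synthetic two-group postmortem cohort
    generator with known ground truth so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
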