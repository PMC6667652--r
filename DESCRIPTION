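Package: chromdyn
Title: Two-Condition Nucleosome and Chromatin-State Dynamics from MNase-Seq
    and ChIP-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tidy pipeline for comparing chromatin organisation between two
    conditions (for example a transcription-factor knockdown versus control).
    Calls nucleosomes from MNase-seq fragment midpoints with Gaussian
    smoothing and an exclusion zone, classifies nucleosome dynamics
    (fixed, shift, eviction, assembly), detects promoter nucleosome-free
    region loss and gain, binarizes histone-modification signal into 200-bp
    bins against an IgG control and segments the genome into four mark-pair
    chromatin states, assigns promoter and enhancer states (active,
    intermediate, poised, primed, off), annotates transcription-factor
    binding and enhancer target genes, and tests independence of promoter and
    enhancer state changes with 2x2 chi-square contingency tables. Includes a
    synthetic-data generator with planted, recorded truth so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
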