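Package: splicescape
Title: Structural and Energetic Signal Profiling at Exon-Intron Boundaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Characterises exon-intron boundary junctions through the
    physico-chemical lens of DNA: fixed-width boundary windows extracted from a
    genome and annotation (or simulated with known ground truth) are encoded
    per dinucleotide step with structural and energetic parameters, smoothed
    with a sliding-window moving average, pooled into average profiles with
    standard errors, and scored for per-sequence junction signals against
    exon-interior controls via an enclosed-area statistic. Companion tools
    compute position-wise base frequencies, information content and consensus
    strings around splice sites, position-specific inter-parameter
    correlations, and a two-group clustering of parameters by their behaviour
    near the junction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ggplot2,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
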