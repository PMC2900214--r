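Package: erosionscan
Title: Genome Erosion Analysis for Reduced Endosymbiont Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Rule-based pseudogene calling from frameshift-aware three-frame
    translated alignment, insertion-sequence remnant detection (de novo
    repeat families, terminal inverted repeats, library homology, fragment
    merging, transposase ORF census), per-replicon genome erosion
    statistics, COG functional-category enrichment testing with Monte-Carlo
    simulated p-values and Pearson residuals, and minimal-gene-set status
    classification. Includes a synthetic genome generator that plants
    truth-tagged erosion events (premature stops, frameshifts, ORF splits,
    truncations, insertion sequences) so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
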