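Package: footgrn
Title: Subtype-Specific Transcription Factor Network Inference from DNase Footprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers mutation-subtype-specific transcription factor (TF) gene
    regulatory networks from stranded DNase I cut profiles. Builds a union
    atlas of DNase I hypersensitive sites (DHSs) from merged cut tracks,
    quantifies samples on fixed 400-bp windows with ranked-peak normalization,
    detects digital footprints with a strand-aware binomial statistic and the
    associated sequencing-depth quality control, condenses redundant motif
    libraries into non-redundant TF-family representatives, links distal DHSs
    to target genes through promoter-capture interaction data with a
    nearest-gene fallback, and assembles subtype-labelled TF networks together
    with a motif co-occupancy permutation test. A synthetic-data generator
    plants a known regulatory landscape so every stage is verifiable against
    ground truth without cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
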