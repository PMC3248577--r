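Package: peakcobind
Title: Transcription-Factor Co-Binding Analysis of ChIP-Seq Peak Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of transcription-factor ChIP-seq experiments
    centred on co-binding: replicate-consistent peak consensus, multi-factor
    and multi-cell-line overlap classification, significance of interval
    overlap via a block-rotation genome structural correction statistic,
    input-subtracted binned signal matrices for heat maps, position weight
    matrix scanning with a permuted-matrix null for windowed motif
    enrichment, promoter/exon/intron/intergenic peak annotation, and
    enrichment of differentially expressed genes near binding sites.
    Includes a fully seeded synthetic-data generator (genomes, binding
    truth, replicate peaks, reads, motifs, expression) so the entire
    pipeline runs end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml,
    Rcpp,
    GenomicRanges,
    IRanges,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
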