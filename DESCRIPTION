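Package: matesv
Title: Structural Variant Discovery from Long-Insert Mate-Pair Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detects deletions, insertions, inversions and interchromosomal
    translocations from long-insert (~2.5 kb) mate-pair alignments.
    Discordant read pairs are classified by separation, orientation and
    chromosome concordance, greedily clustered into candidate structural
    variants, and passed through a somatic filter cascade (healthy-control
    subtraction, proximity to assembly gaps/telomeres/centromeres, known
    germline variants, read support, matched-normal subtraction). Candidate
    interchromosomal events are screened with an anchor-position correlation
    statistic that separates genuine translocations from repeat-driven
    artifacts. Breakpoints are annotated against gene models in
    exon/intron style, and cohort-level statistics (exact log-scale binomial
    region-overlap enrichment, gene-set enrichment, validation-table
    aggregation) are provided, together with a coordinate-level mate-pair
    simulator for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
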