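Package: transwalker
Title: Transcriptome Walking Assembly and Cauchy-Tail Differential
    Expression for Two-Condition RNA-Seq
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Reference-free analysis of two-condition bulk RNA-seq built
    around the "transcriptome walking" assembler: paired-end reads are
    quality-groomed to contiguous high-Phred runs, screened either by an
    identical-read census between conditions or by six-frame translated
    BLOSUM search against protein queries, and assembled one consensus
    base at a time from exactly overlapping reads with per-column SNP
    records.  Per-transcript expression is quantified by counting reads
    matching the open reading frame at a 90/100 identity criterion,
    normalised by frame length and by a reference transcript, and
    between-condition abundance ratios are modelled with a least-squares
    Cauchy fit to their histogram; transcripts in the lower and upper 5%
    tails of the fitted cumulative distribution are called as affected.
    Includes a paired-end read simulator with planted ground truth and a
    bundled 500-transcript locust auditory-organ abundance dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    dplyr,
    graphics,
    jsonlite,
    Rcpp,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
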