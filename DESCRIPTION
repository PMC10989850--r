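Package: seqscrub
Title: One-Pass FASTQ Preprocessing, Quality Control, and Deduplication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A one-pass preprocessing toolkit for short-read FASTQ data.
    Reads are split into fixed-size packs that are routed to workers by a
    deterministic rule and reassembled in input order, so output is
    byte-identical for any worker count. Implements adapter trimming by
    paired-end overlap analysis and by adapter sequence, sliding-window
    quality trimming, polyG/polyX artifact trimming, quality/N/length read
    filtering, UMI extraction, quality-aware base correction, paired-end
    merging with insert-size estimation, bloom-filter exact-duplicate
    detection with an analytic false-positive correction, per-cycle quality
    and base-content statistics, overrepresented-sequence analysis, and
    JSON/HTML quality-control reports. A seeded synthetic read-pair
    generator with full ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    jsonlite,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
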