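Package: fusionprior
Title: Filtering and Prioritization of Gene Fusion Candidates from RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A sample-centered cascade for shrinking the candidate lists
    produced by chimeric-transcript discovery tools (deFuse-, ChimeraScan-
    and MapSplice-style callers) down to a short list of priority gene
    fusions. Caller outputs in several tab-separated dialects are
    harmonized to 1-based coordinates, same-tool duplicates are collapsed,
    fusions with unannotated partner genes, fusions shared with healthy
    control samples, and fusions lacking split-read support are removed
    with full per-stage provenance. For every surviving fusion four
    virtual junction references are reconstructed from breakpoint-flanking
    genomic sequence and matched against split reads or the caller
    consensus to classify the fusion structure (promoter/3'-end retention
    on each side); structurally reliable fusions and fusions with a high
    external driver score are marked as priority. A deterministic
    simulator generates toy genomes, fusions of every structural class and
    caller files with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    stats,
    tools,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
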