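Package: poolRSV
Title: Rare-Variant Discovery from Pooled DNA Sequencing with Carrier Decoding and Burden Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for rare sequence variant (RSV) discovery in overlapping-pool
    DNA sequencing designs. Implements construction and validation of
    two-replicate pool designs, simulation of per-pool pileup count tables with
    planted variants and sequencing artifacts, a Phred-scaled binomial
    likelihood-ratio caller for low-allele-fraction variants with base-quality,
    strand-bias, allele-fraction and coverage filters, carrier identification by
    pool intersection, a rule-based prioritization cascade (consequence,
    population frequency, Condel/CADD deleteriousness, gene constraint), and
    case-control carrier-burden statistics (proportion ratios, odds ratios and
    an exact two-sided 2x2 test), together with an end-to-end pipeline and
    sensitivity/specificity evaluation against simulation truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    rtracklayer,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    VariantAnnotation
Config/testthat/edition: 3
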