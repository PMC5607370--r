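Package: ncostmin
Title: Transcriptomic Nitrogen Cost Minimization from Differential 5' End Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and classifies bacterial transcription start sites (TSSs) from
    5'-end read coverage of TSS-enriched versus non-enriched dRNA-seq libraries using a
    Skellam test on count differences, quantifies internal-transcription dynamics between
    nitrogen-replete and nitrogen-deprived conditions, derives truncated protein isoforms
    implied by internal TSSs (nearest downstream in-frame methionine) and accounts their
    nitrogen savings, and computes genome-scale motif statistics: glycine-glycine codon-pair
    observed:expected ratios binned by anti-Shine-Dalgarno affinity, pyrimidine-rich k-mer
    enrichment with Fisher's exact tests, and NtcA promoter-box scans upstream of
    translational starts. Ships a synthetic-data generator with planted ground truth so the
    whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
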