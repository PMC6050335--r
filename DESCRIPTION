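Package: m6Ajunction
Title: Structural Context Analysis of N6-Methyladenosine Sites in RNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the secondary-structure context of
    N6-methyladenosine (m6A) sites in RNA. Provides a simplified
    nearest-neighbor folding engine with exhaustive suboptimal-structure
    enumeration, classification of focal adenosines into junctional, duplex
    and unpaired motif categories (including the 5' bulge junctional A-U
    motif), population surveys of site sets across free-energy thresholds,
    two-state van't Hoff fitting of UV melting curves with methylation
    difference energetics, one-site and two-independent-site fluorescence
    polarization binding fits, and seeded generators for synthetic
    transcripts, melting curves and titrations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
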