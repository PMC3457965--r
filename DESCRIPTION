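Package: hseprobe
Title: Probe Specificity Prediction for Allele-Specific Extension Reactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and evaluation of allele-specific extension probes for
    haplotype-specific extraction (HSE) of DNA mixtures. Implements a
    nearest-neighbor thermodynamic engine for matched and single-mismatch
    DNA duplexes (free energy, melting temperature, and two-state
    equilibrium duplex concentration), simulates the match-minus-mismatch
    duplex-concentration curve (delta-con) over a 5'-trimmed probe-length
    series to select the most discriminating probe length, screens probes
    for off-target binding sites with an extendable 3' end, and ships
    curated experimental probe tables for concordance analysis between
    predicted and experimentally optimal probe lengths.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
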