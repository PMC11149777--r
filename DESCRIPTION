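Package: denovostruct
Title: Structural Evolution Rates of De Novo Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how newly originated (de novo) proteins
    change in structure over short evolutionary timescales, using gene
    duplicates as the comparison class. Computes per-protein descriptors
    (intrinsic disorder fraction, STRIDE secondary-structure proportions,
    amino-acid composition, molecular weight, net charge and isoelectric
    point, hydrophobicity, MoRF fraction, pLDDT folding-confidence class),
    synteny-based gene ages from reciprocal best hits, protein-complex
    interface contact statistics and binding free-energy conversions,
    Pearson coexpression partner selection, and branch-median-versus-
    divergence-time regression for rate estimation. A synthetic-data
    generator with planted ground truth emulates every input so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
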