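Package: venomtx
Title: Venom-Gland Transcriptome Annotation and Toxin Discovery
Version: 0.1.0
Authors@R: person("Venomtx", "Maintainers", email = "maintainers@venomtx.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for annotating venom-gland
    transcriptomes assembled de novo: six-frame ORF translation with
    best-candidate selection, homology-based quality filtering on
    matched-length ratios (ML/BL, ML/PL) and percent identity, RPKM
    quantification from alignments or count tables, three-strategy
    toxin discovery (homology to known toxins, domain-architecture
    matching, cysteine-spacing pattern alignment), and hypergeometric
    pathway enrichment.  Ships a synthetic-data generator with known
    ground truth so every stage is testable without external databases
    or sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
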