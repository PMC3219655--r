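Package: ocmirnet
Title: miRNA-Centred Regulatory Network Analysis for Ovarian Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds heterogeneous miRNA-transcription-factor regulatory
    networks from association tables (verified miRNA-target pairs, disease
    gene lists, transcription-factor binding-site hits in miRNA promoters,
    transcription co-factor interactions, and protein-protein interactions),
    ranks nodes by a stochastic edge-weight influence score averaged over
    repeated weight draws, enumerates self-loop and three-element feedback
    loop regulatory motifs, and compares pathway membership of loop-involved
    genes against a disease-gene background with an exact hypergeometric
    test. Includes a synthetic-data generator with a ground-truth ledger so
    the full pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
Config/testthat/edition: 3
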