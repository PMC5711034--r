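Package: allosim
Title: Simulation of Donor T Cell Alloreactivity Potential from Exome-Derived
    Minor Histocompatibility Antigens
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Derives graft-versus-host-direction (recipient-present,
    donor-absent) coding variants from paired donor/recipient VCFs, builds
    the candidate minor histocompatibility antigen (mHA) 9-mer peptide
    library (17-mer contexts around each nonsynonymous variant, plus
    Y-chromosome peptide tiling for female-to-male pairs), attaches HLA
    class I binding affinities (IC50, nM) from predictor output tables or a
    deterministic synthetic affinity model, joins per-tissue gene expression
    (RPKM) to build organ-specific alloreactivity operators, and simulates
    donor CD8+ T cell clonal repertoires as an iterated logistic
    vector-operator dynamical system with affinity-exponent carrying
    capacities, Lotka-Volterra inter-clonal competition, and
    tissue-expression weighting. Includes model extensions (antigen
    presenting cell effect vector, regulatory T cell growth-rate switching,
    TCR-affinity exponent, multiset combinatorial presentation probability)
    and a fully synthetic donor-recipient-pair cohort generator so the
    entire pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    Biostrings,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
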