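Package: chaperonet
Title: Regulatory Classification of the C. elegans Muscle Chaperone Network
Version: 1.0.0
Authors@R: person("Proteostasis", "Lab", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrates transcription-factor occupancy calls, muscle-expression
    evidence and literature-curated functional annotations over a fixed
    catalog of C. elegans chaperone genes. Provides evidence-count ranking
    and four-group regulatory classification, exact one-sided set-overlap
    statistics (hypergeometric/Fisher) with Venn region counts, developmental
    time-course normalization, hierarchical clustering and myogenesis-induced
    (MI) pattern classification, E-box (CANNTG) promoter scanning in both
    consensus and PWM modes including exact score-distribution p-values,
    and relative qPCR quantification by the 2^-ddCt method with exact
    Mann-Whitney comparisons. A seeded synthetic-data module generates every
    input class with known ground truth, and a pipeline orchestrator runs
    all stages from one configuration file.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    S4Vectors,
    GenomicRanges
Config/testthat/edition: 3
RoxygenNote: 7.3.3
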