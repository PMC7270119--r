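Package: hetexpress
Title: Heterosis and Expression-Mode Analysis for Parent-Hybrid Trios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies hybrid vigor in parent-hybrid trios and classifies the
    inheritance mode of gene expression. Computes mid-parent and high-parent
    heterosis for phenotypic traits, calls differentially expressed genes
    between an F1 hybrid and each inbred parent from FPKM-like abundance
    matrices using a signed fold-change convention, derives common and
    universal DEG sets across two independent crosses, assigns each gene to
    one of twelve additive/dominance/overdominance expression classes, and
    validates expression direction with qPCR relative quantification
    (2^-ddCt). A synthetic trio simulator with known ground-truth classes
    makes every stage testable without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: jsonlite, stats, utils, tools
Suggests: testthat (>= 3.0.0), optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
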