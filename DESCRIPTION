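Package: endoamp
Title: Taxon-Specific 16S rRNA Primer Design and Endozoicomonas Amplicon
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for detecting and characterizing the coral
    symbiont genus Endozoicomonas in 16S rRNA amplicon surveys. Implements
    degenerate-primer matching with deliberate-mismatch primer engineering
    and in-silico PCR evaluation (sensitivity/specificity), 454-style read
    quality control and barcode demultiplexing, bimera screening, an
    RDP-style naive-Bayes k-mer classifier with bootstrap confidence and
    multi-database rescue, dereplication and unique-ribotype profiling,
    greedy 97% OTU clustering, rarefying and alpha diversity (including a
    singleton-ratio richness statistic and Shannon-based evenness), and
    Kimura 2-parameter divergence with neighbor-joining trees. A synthetic
    community generator with full ground truth makes every stage testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    vegan,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
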