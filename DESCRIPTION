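Package: hicloops
Title: Topological Classification of CTCF-CTCF Hi-C Submatrices and Loop Calling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised topological classification of CTCF-CTCF Hi-C
    interaction submatrices with a self-organizing feature map, clustering of
    the resulting neurons into interaction-pattern classes, functional
    characterization of the classes by chromatin state, compartment and motif
    orientation, and a neural-network chromatin-loop caller trained on the
    loop/no-loop classes. Includes a synthetic Hi-C data generator (distance
    decay, planted loops, checkerboard compartments, stranded peak lists and
    chromatin-state tracks) so the whole pipeline is testable end to end, plus
    reproducibility (Jaccard) and biological-relevance benchmark metrics for
    loop-call sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
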