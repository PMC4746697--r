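Package: natphase
Title: Natural Antisense Transcript Discovery and Phased nat-siRNA
    Detection from De Novo Assembled Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts natural antisense transcript (NAT) pairs directly from
    de novo assembled transcripts of organisms without a reference genome,
    validates the annealing potential of each candidate pair at the duplex
    structure level, and searches the perfectly annealed regions for
    phase-distributed nat-siRNA clusters with the 2-nt 3' overhang duplex
    geometry left by Dicer-like processing. Degradome (PARE) libraries can be
    used to attach 5'-end processing evidence to the phased siRNAs. Includes a
    deterministic synthetic-data generator so every stage is testable without
    external downloads, and a thin command-line interface over the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
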