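Package: polyssr
Title: Candidate Polymorphic Microsatellite Discovery from Multiple Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies candidate polymorphic simple sequence repeats (PolySSRs)
    from multiple assembled genomes or transcriptomes of one species or genus.
    Perfect SSRs (motif length 2-6) are detected on a reference assembly, their
    flanking sequences are located in every other assembly with a built-in k-mer
    seed-and-extend aligner, and each locus is scored by the standard deviation
    of its repeat counts across assemblies (dispersion degree) and by its missing
    rate. Surviving loci receive deterministically designed PCR primer pairs whose
    binding-region conservation across assemblies is reported as a transferability
    score. A synthetic-assembly simulator with a machine-readable truth table
    provides a self-contained validation surface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    methods,
    parallel,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
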