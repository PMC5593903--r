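Package: famsig
Title: Conservation, Coevolution and Subfamily Signatures in Protein Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Profiles residue conservation in protein multiple sequence
    alignments, detects coevolved residue sets by a frequency-increase rule
    screened with exact hypergeometric tests, and classifies sequences into
    familial subgroups using residue signatures, with presets for the
    arsenate reductase (ArsC) and arsenite oxidase molybdopterin (AioA)
    families. Translated amplicons are mapped onto reference residue
    numbering and summarised as sequence-logo frequency tables with
    Bayesian credible intervals. Clone libraries are clustered into OTUs at
    an identity cutoff and summarised with Good's coverage. A synthetic-data
    generator with planted subfamily structure supports end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
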