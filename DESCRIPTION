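Package: cag2caa
Title: CAG-to-CAA Base-Editing Analysis for the HTT Repeat Locus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing cytosine base-editing strategies that
    convert CAG codons to CAA in the huntingtin (HTT) trinucleotide repeat.
    Provides repeat-allele structure arithmetic (canonical, loss of
    interruption, duplicated interruption; glutamine and uninterrupted-CAG
    lengths), guide-RNA register enumeration with PAM classification and
    editing-window mapping, quality control and codon-wise conversion
    calling for paired amplicon reads, least-squares estimation of
    interruption-structure effects on age-at-onset, expansion-index
    quantification of somatic repeat instability, and seeded simulators for
    every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
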