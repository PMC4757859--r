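Package: gibsim
Title: Design and Simulation of Modular Gibson Assembly Cloning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning and simulating modular Gibson assembly
    cloning built around five fixed 30-nucleotide overlap sites that define
    positional slots for promoters and genes. Provides a part registry with
    slot-grammar validation and design enumeration, overhang primer design
    with nearest-neighbor melting temperatures and PCR simulation, one-pot
    isothermal assembly simulation of circular constructs, restriction
    digest prediction and diagnostic enzyme ranking for clone screening,
    sequencing-primer junction coverage, reaction pipetting math, and
    colony-screening statistics. Includes a seeded generator of synthetic
    parts and backbone plasmids for fully offline workflows, FASTA and
    GenBank input/output, and a command-line interface.
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
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
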