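Package: basicbuild
Title: Planning and In-Silico Simulation of Automated BASIC DNA Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compiles CSV construct designs and 96-well source-plate maps for
    BASIC (Biopart Assembly Standard for Idempotent Cloning) DNA assembly into
    validated, volume-exact liquid-handling plans and scripts for the four
    BASIC steps: clip reactions, magnetic-bead purification, annealing
    assembly, and heat-shock transformation with agar spotting. Includes an
    in-silico assembly simulator that models methylation-aware Type IIS
    (BsaI) digestion, half-linker ligation and 21-base overhang annealing to
    predict final construct sequences and verify the idempotent standard, and
    a fixture generator that expands factorial operon-library designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
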