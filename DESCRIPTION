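Package: forkpcr
Title: In Silico Fork PCR Genome Walking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and simulation toolkit for fork PCR genome walking.
    Generates fork primer sets (primary fork primer, secondary fork primer
    and a universal branch primer sharing a 21-nt stem / 20-nt branch
    architecture) and nested site-specific primer triples under
    melting-temperature, base-composition, run-length and secondary-structure
    constraints; predicts, for any template sequence, which products the
    three nested walking rounds amplify, suppress by terminal-inverted-repeat
    hairpin formation, or dilute; and emits the bench thermal programs and
    reaction recipes. Includes a seeded synthetic-genome fixture generator
    with closed-form expected amplicon sizes, a virtual gel report, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
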