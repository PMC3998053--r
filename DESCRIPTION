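Package: molmorph
Title: Molecular Morphing and Chemical Space Exploration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Systematic exploration of chemical space by molecular morphing.
    Given a start and a target molecule, small structural mutation operators
    (add/remove atom, add/remove bond, mutate atom, bond reroute, bond
    contraction, interlay atom) are applied iteratively, guided by fingerprint
    distance to the target, to produce a connected path of valid molecules
    between the two. Includes molecular-weight and synthetic-accessibility
    filtering, decoy-biased scoring, neighbourhood generation around a
    molecule of interest, 2D layouts of the exploration tree (PCA and
    Kamada-Kawai), a batch command-line interface, a benchmark harness, and a
    synthetic start/target pair generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: OpenBabel (>= 3.0, the 'obabel' executable on PATH)
Config/testthat/edition: 3
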