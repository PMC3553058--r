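Package: molcode
Title: Detecting Molecular Codes in Chemical Reaction Networks
Version: 0.1.0
Authors@R:
    person("Maintainer", "Molcode", email = "molcode@example.org", role = c("aut", "cre"))
Description: Tools to assess the semantic capacity of a chemical reaction
    network, i.e. its ability to implement contingent sign-to-meaning
    mappings (molecular codes). Provides the reaction-network closure
    operator and lectic closed-set enumeration, two detectors for binary
    molecular codes (closure-based and k-shortest-path based), semantic
    capacity measures, constructors for reference model chemistries
    (genetic-code translation with and without aminoacyl-tRNA synthetases,
    transcription-factor gene regulation, phosphorylation cascades), a
    random bimolecular network null model with density surveys and network
    randomization, and a minimal mass-action simulator for
    concentration-level codes in signaling cascades.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
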