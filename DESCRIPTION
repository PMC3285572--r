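Package: abrkit
Title: Structural-Consensus Identification of Antibody Antigen-Binding Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives antibody antigen-binding regions (ABRs) from contact
    consensus across structurally aligned antibody-antigen complexes,
    transfers those regions to new antibodies from sequence or structure via
    framework-anchored local alignment, numbers antibody variable domains
    under the Kabat, Chothia and IMGT conventions to extract CDRs, curates
    non-redundant annotated reference sets from pools of complexes, and
    evaluates region definitions against observed binding residues
    (precision/recall, consensus and method-specific residue sets, ddG
    classification of alanine-scan results). Includes a synthetic-complex
    generator so the whole pipeline is testable without structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
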