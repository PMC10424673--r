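Package: ridesign
Title: Retro-Inverso D-Peptide Design by Mirror-Image Fragment Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing retro-inverso d-peptide analogues of
    alpha-helical peptide agonists. Implements the mirror-image fragment
    search strategy: a scaffold helix is split into overlapping segments,
    binding hotspots on each segment define combinatorial atom-level query
    structures, a mirrored (d-PDB style) fragment library is scanned with
    least-squares proper-rotation superposition, and the best matches are
    spliced into a single d-peptide model placed on the mirrored scaffold
    frame. Includes deterministic synthetic-structure generators (ideal
    helices, planted matches) so the whole pipeline is testable without
    external structure downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
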