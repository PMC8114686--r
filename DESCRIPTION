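Package: sbgndyn
Title: Qualitative Dynamics of SBGN Process Description Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Toolkit for working with SBGN Process Description (PD) reaction
    maps at the conceptual level: reading and writing SBGN-ML, importing
    CellDesigner (extended SBML) maps, scripted harmonization and merging of
    maps, and a qualitative Boolean interpretation ("general semantics") that
    turns a PD map into an asynchronous automata network. On the resulting
    networks the package performs exact explicit-state reachability analysis,
    phase-progression validation against cycle marker tables, minimal
    precursor-state computation, and screens for loss-of-function and
    gain-of-function mutation sets that block checkpoint markers.
License: MIT
Encoding: UTF-8
Imports:
    xml2,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
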