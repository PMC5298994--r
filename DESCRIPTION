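Package: poreperm
Title: Hemichannel Permeability Analysis via Descriptor Subset Selection,
    Pore Profiling and Functional Assay Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to characterize connexin hemichannel permeability from
    three directions: selection of molecular-descriptor subsets that separate
    permeant from non-permeant fluorescent tracers, using an elitist genetic
    algorithm with leave-one-out K-nearest-neighbor fitness; fixed-axis
    pore-radius profiling of channel structures from PDB coordinates; and
    quantification of electrophysiology and imaging assays (junctional
    conductance, single-channel event idealization, unitary conductance and
    open probability, dye-uptake slopes, ratiometric calcium signals).
    Includes the published 16-dye permeability panel and 9x11 descriptor
    table as packaged fixtures, and seeded generators for synthetic
    descriptor matrices, single-channel traces, uptake time courses and
    pore geometries.
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
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
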