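Package: g4topo
Title: Topology Annotation and Geometric Analysis of Intramolecular
    G-Quadruplex Structures
Version: 0.1.0
Authors@R:
    person("g4topo", "maintainers", email = "g4topo@example.org",
           role = c("aut", "cre"))
Description: Annotates three-dimensional structures of intramolecular
    G-quadruplexes (G4s). Detects G-tetrads from Hoogsteen hydrogen-bond
    geometry, assembles the stem with clockwise strand numbering, derives
    the strand-direction topology (parallel, antiparallel-chair,
    antiparallel-basket, antiparallel-basket2 and the four hybrids),
    glycosidic syn/anti patterns, groove-width signatures, loop taxonomy
    (propeller, lateral, diagonal, internal) with progression signs,
    discontinuities (bulges, snapbacks, two-block layouts), V-shaped
    strands and stem-extremity sides. Includes a quantitative geometric
    model for loop spans and diagonal-loop feasibility, a rule engine
    mapping loop-length triples to allowed topologies, dataset-level
    summaries with non-redundant sequence accounting, and a generator of
    idealized G4 coordinate models with known ground truth for
    download-free testing. Reads PDB and mmCIF; writes JSON and TSV
    reports; ships a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
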