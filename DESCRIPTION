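Package: chlorofba
Title: Constraint-Based Analysis of Chlorophyll Biosynthesis in a Leaf Cell
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Flux balance analysis of compartmented plant metabolic
    networks, centred on chlorophyll biosynthesis in a rice leaf cell.
    Provides a plain-text reaction format with an SBML importer, a
    flux-minimising linear-programming engine with a bundled deterministic
    simplex solver, flux variability analysis at strict and relaxed
    optima, single-reaction and gene deletion essentiality scans,
    declarative scenario definitions (Rubisco carboxylase/oxygenase
    coupling, ammonia-transporter scans, chloroplastic glutamine
    synthetase experiments), energy- and redox-conservation validation,
    and a curated reduced four-compartment leaf network plus a synthetic
    network generator for property-based testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xml2,
    yaml
Suggests:
    pracma,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
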