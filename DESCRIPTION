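Package: BarrierScreen
Type: Package
Title: Systematic Activation-Barrier Screening of Enzyme Active-Site Mutants
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Orchestrates systematic in silico screening of enzyme
    active-site mutants by activation-barrier estimation. The reaction
    barrier of the rate-limiting chemical step is mapped by adiabatic
    mapping: constrained linear interpolation between the enzyme-substrate
    (ES) and covalent-intermediate (GE) endpoint structures along a single
    interatomic reaction coordinate, with every frame relaxed by a pluggable
    energy engine. Includes PDB-backed structure handling, exhaustive
    active-site mutant enumeration with deterministic side-chain
    construction, endpoint-derivation pathways, a bit-exact MOPAC-dialect
    input writer and tolerant output parser, validity filters (Lewis-structure
    failure, total-charge mismatch, close contacts, walltime), barrier
    extraction and ranking, double-mutant additivity analysis, and
    transition-state-theory rate conversion. An analytic surrogate energy
    surface with programmable per-mutant barriers makes the full pipeline
    testable without any quantum-chemistry program.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'structure-io.R'
    'geometry.R'
    'sidechain-templates.R'
    'mutagenesis.R'
    'mutants.R'
    'pathway.R'
    'engine-mopac.R'
    'engine-surrogate.R'
    'barriers.R'
    'screen.R'
    'toy-system.R'
    'BarrierScreen-package.R'
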