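Package: lssmf
Title: Linear-Scaling Systematic Molecular Fragmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Engine for linear-scaling systematic molecular fragmentation
    of large molecules. Perceives bond orders from interatomic distances and
    covalent radii, partitions atoms into functional groups, enumerates
    bonded fragments at a chosen level with signed integer
    inclusion-exclusion coefficients obeying chemical balance, generates
    nonbonded dimer and three-body fragments under distance-based or
    covalent-radius-ratio cutoffs, caps severed bonds with hydrogen link
    atoms, emits per-fragment geometry jobs for external quantum-chemistry
    engines, and assembles total energies from per-fragment energy records.
    Includes deterministic alkane fixture generators and an additive toy
    energy backend so every stage is verifiable in closed loop.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, igraph, bio3d, yaml
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
Collate:
    'AllClasses.R'
    'lssmf-package.R'
    'AllGenerics.R'
    'elements.R'
    'molecule-io.R'
    'connectivity.R'
    'bonded.R'
    'nonbonded.R'
    'capping.R'
    'energy.R'
    'fixtures.R'
    'pipeline.R'
    'show-methods.R'
RoxygenNote: 7.3.3
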