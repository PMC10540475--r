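Package: pkaqsar
Title: Basic pKa Prediction for Nitrogen Compounds from Quantum-Derived Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts basic pKa values of nitrogen-containing compounds from
    six quantum-chemistry-derived molecular descriptors via a published
    multiple linear regression, and provides the full toolchain around it:
    readers and writers for species-level quantum-chemistry results and
    Gaussian cube volumetric grids, electronic descriptors (deprotonation
    energy, HOMO-LUMO gap change, Mulliken electronegativity from vertical
    ionization potential and electron affinity), marching-tetrahedra
    extraction of the 0.001 au isodensity surface with electrostatic-potential
    mapping for the nonpolar surface area percentage, average local ionization
    energy condensed onto the reactive nitrogen, an ordinary-least-squares
    QSAR engine with leave-one-out cross-validation and all-subsets descriptor
    selection, external validation against packaged reference tables including
    cucurbit[7]uril host-guest pKa shifts, and deterministic synthetic-fixture
    generators with closed-form ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
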