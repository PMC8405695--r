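Package: CorneaBiomech
Title: Corneal Biomechanics from Optical Coherence Elastography and 2D Extensometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies murine corneal biomechanical properties from two
    complementary measurement modalities. Quasi-static phase-difference
    optical coherence elastography (OCE): complex cross-correlation of
    reference/deformed B-scan pairs, depth-adjacent phase differencing to
    axial strain, corneal segmentation for central thickness, and thin-shell
    (Laplace) stress conversion to an elastic modulus. 2D extensometry:
    force/indenter-travel traces converted to tensile stress and strain,
    three-phase protocol segmentation, stress-relaxation quantification,
    constrained 3-term Prony-series fitting, and the 10-15 percent
    strain-window modulus. Includes a synthetic-data module (speckle B-scan
    phantoms with known imposed strain, Prony-model force traces, two-group
    cohorts) so every stage is verifiable by parameter recovery, and a
    normality-gated two-sample statistical workflow for cohort comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    tiff,
    minpack.lm,
    pracma,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'constants.R'
    'synthetic.R'
    'oce.R'
    'extensometry.R'
    'cohort.R'
    'io.R'
    'pipeline.R'
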