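Package: mesoSAXS
Title: Mesophase Indexing and Curvature Analysis for 1D SAXS Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of one-dimensional small-angle X-ray scattering (SAXS)
    profiles from self-assembled peptide-DNA complexes and peptide-remodeled
    lipid membranes. Provides Bragg peak detection and nonlinear line-shape
    fitting (Lorentzian and squared-Lorentzian), reflection catalogs and
    lattice-parameter regression for lamellar, square/hexagonal/tetragonal
    columnar and Pn3m bicontinuous cubic mesophases, Warren-type
    nanocrystalline domain-size estimation from peak widths, negative
    Gaussian curvature quantification from cubic lattice parameters,
    sequence-level amphipathicity and charge-density metrics for helical
    peptides, and a seeded synthetic powder-spectrum generator for
    ground-truth benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, minpack.lm, jsonlite
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'profile-io.R'
    'peakfit.R'
    'phase-catalog.R'
    'indexing.R'
    'microstructure.R'
    'curvature.R'
    'peptide-features.R'
    'synthetic-data.R'
    'pipeline.R'
    'data-tables.R'
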