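Package: cryovertex
Title: Symmetry-Free Localization of the Unique Portal Vertex in
    Icosahedral Virus Cryo-EM Reconstructions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale single-particle reconstruction toolkit for
    resolving the unique genome-packaging vertex of icosahedral,
    membrane-containing viruses. Builds synthetic virion, procapsid and
    packaging-mutant density phantoms with an internal lipid shell, a
    12-fold external portal and a 6-fold transmembrane conduit; simulates
    noisy projection stacks with ground truth; determines icosahedral
    orientations by exhaustive projection matching with a
    consistency-based particle filter; resolves the 60-fold orientation
    ambiguity (12 vertices x 5 attachments) by masked-library scoring or
    by anchoring on the 11 regular five-fold vertices; reconstructs
    unsymmetrized maps by direct Fourier inversion with gold-standard
    half-set handling; and provides map metrology (unmasked Fourier shell
    correlation and resolution criteria, matched-resolution difference
    maps, rotational-correlation symmetry detection, radial profiles and
    FWHM shell extents, relative membrane intensity, and density
    volume-to-mass conversion).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
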