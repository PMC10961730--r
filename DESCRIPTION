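Package: helixcd
Title: Ensemble Estimation of Peptide Helicity from Circular Dichroism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the helix content of peptides from circular dichroism
    (CD) measurements at 222 nm using an ensemble model. A composition-resolved
    Lifson-Roig helix-coil engine enumerates conformer classes of a peptide
    chain exactly, and three spectroscopic models (linear, empirical and
    dichroic helix-length corrections) map ensemble compositions to mean molar
    ellipticity per peptide unit. Provides inversion of a measured ellipticity
    to helicity, global fitting of thermal-melt and fully-helical reference
    data under a Gaussian noise model (maximum likelihood and affine-invariant
    MCMC backends), synthetic melt simulation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    stats,
    utils,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
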