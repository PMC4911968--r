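Package: conjview
Title: Planar Kidney Activity Quantification from SPECT/CT Phantoms
Version: 0.1.0
Authors@R: person("Conjview", "Developers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Evaluates conjugate-view and posterior-view planar estimates of
    kidney activity concentration in 177Lu radionuclide therapy imaging.
    Builds labelled synthetic SPECT/CT torso phantoms, converts CT Hounsfield
    volumes to 208 keV attenuation maps, forms attenuated anterior/posterior
    planar projections, constructs kidney, column, true-background and sector
    background regions of interest automatically, and reports
    background-to-true-background ratios, negative-net-count fractions and
    relative activity concentrations across cohorts of phantoms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
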