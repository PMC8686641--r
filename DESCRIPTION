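Package: palaterelief
Title: Selective Relief Simulation for Palatal Plates by Finite-Element
    Stress Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the mechanical effect of relief (an intentional gap
    between a palatal plate and the underlying mucosa) on the stress borne
    by denture-supporting mucosa.  Provides a parametric synthetic palate
    generator (plate layer plus a mucosa layer with a 14-segment thickness
    map), a structured tetrahedral mesher with conforming plate-mucosa
    interface, a small-strain isotropic linear-elastic tet4 finite-element
    solver with von Mises stress recovery, borderline-thresholded and
    mid-palatal relief procedures realized by interface decoupling, and
    stress-volume distribution metrics reported as ratios against a
    no-relief baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    ggplot2,
    stats,
    utils,
    grDevices,
    xml2,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
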