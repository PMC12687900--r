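Package: sonovessel
Title: Reduced-Order Simulation of Microbubble Cavitation in Compliant Microvessels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled radial dynamics of one or two ultrasound-driven gas
    microbubbles in shear-thinning blood, with one-way-coupled estimates of
    the microstreaming shear stress, acoustic normal stress, and lumped
    elastic response of a microvessel wall, mapped through an empirical
    endothelial shape-index law to paracellular permeability. Includes
    scenario configuration files, parameter-sweep drivers over acoustic
    pressure, frequency, bubble size and inter-bubble spacing, and a
    comparison of single- versus two-bubble systems, targeting the
    stable-cavitation regime used in ultrasound-mediated drug delivery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
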