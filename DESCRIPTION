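Package: helixkin
Title: Kinematics of Spinning and Helical Swimming in Salp Chains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of in situ three-dimensional swimming kinematics of
    colonial salp chains. Reads digitized landmark tracks, removes background
    water/camera motion by reference-particle subtraction, fits circular
    helices to motion-corrected trajectories (orbit radius, pitch, angular
    frequency, handedness), measures spin direction and angular velocity about
    the chain axis, classifies recordings into spinning, transition and
    helical swimming modes, computes siphon/jet angles relative to the chain
    axis and jet Reynolds numbers, and evaluates a minimal rigid-chain
    multi-jet thrust/torque (wrench) model linking oblique jet orientation to
    spin handedness. Includes a ground-truth-labelled synthetic trajectory
    generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
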