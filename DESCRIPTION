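Package: mantisstereo
Title: Correspondence-Free Stereopsis Models of Insect Binocular Vision
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates two correspondence-free stereoscopic mechanisms inspired
    by praying-mantis vision: a two-layer binocular network that selects head
    saccade targets with a bias towards stereoscopically nearer objects, and a
    single centre-surround disparity sensor that triggers predatory strikes.
    Includes the Fick-coordinate binocular viewing geometry, a synthetic-scene
    generator that renders spherical targets onto lat-long retinal grids,
    dichoptic stimulus builders (moving discs, ghost pairs, vertical-disparity
    stimuli), toy demonstrations of ideal/strong/weak stereo correspondence,
    and reproducible behavioural experiment runners.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
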