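Package: transpirest
Title: Transpiration Resistance Determination for Fruit and Vegetables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Determines the water-vapour transport resistances of fruit and
    vegetables from differential-weighing and climate logs. Implements the
    psychrometric relations of humid air (saturation and partial vapour
    pressure, mixing ratio, density, volume-related water content) forward
    and inverse, allometric surface-area regressions for seven produce
    types, estimation of the area-related transpiration rate from precision
    weighings, partitioning of the total resistance into tissue and
    boundary-layer components under free-convection, forced-convection,
    wetted-surface and bulk protocols, recovery of the humidity at the
    produce surface, Arrhenius temperature adjustment of resistances, and a
    forward simulator that generates synthetic weighing and climate logs
    with known resistances for end-to-end parameter-recovery testing.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
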