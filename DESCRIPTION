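Package: nanoprecip
Title: Nucleation, Growth and Aggregation Modelling for Antisolvent
    Precipitation of Excipient-Free Nanodrugs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Physicochemical model chain for the staged antisolvent
    precipitation of excipient-free drug nanoparticles: supersaturation,
    classical nucleation theory (critical radius, energy barrier,
    nucleation rate), Smoluchowski collision kinetics,
    Henderson-Hasselbalch ionization and pH-dependent weak-base
    solubility, plus a seeded staged-addition population simulator that
    emulates dynamic-light-scattering size series and a size-versus-logP
    regression analysis of the resulting final hydrodynamic diameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
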