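Package: spindlescale
Title: Stoichiometric Modeling and Quantification of Mitotic Spindle Scaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulation and quantification toolkit for anaphase spindle
    elongation and chromosome segregation in early embryonic cells. Implements
    a stoichiometric model of cortical pulling forces, in which minus-end
    directed motors anchored on a spherical cell surface bind astral
    microtubules one-to-one and pull on the spindle poles, with a viscous
    coupling between each pole and its chromosome plate and an imposed
    exponential chromosome-separation law. Provides differential-evolution
    inference of the microtubule catastrophe rate from pole-to-pole
    trajectories, sigmoid and exponential trajectory fitting with derived
    elongation and segregation rates, power-law scaling regressions and
    piecewise transition fits versus cell size, kymograph peak tracking,
    laser-ablation velocity-window analysis, classification of
    electron-tomography microtubule traces, and seeded synthetic-data
    generators for every input the analyses consume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
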