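Package: poroknee
Title: Fibril-Reinforced Biphasic Finite-Element Simulation of Tibiofemoral Contact
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-dimensional coronal-plane finite-element model of the
    tibiofemoral joint for studying time-dependent (creep) contact mechanics of
    articular cartilage and meniscus. Tissues are fibril-reinforced biphasic
    (poroelastic) continua solved with a mixed displacement-pressure
    formulation; contact between biphasic surfaces uses a penalty method with
    automatic switching between pressure-continuous (sealed) conditions inside
    the contact patch and free-draining conditions outside it. Includes a
    synthetic joint-geometry generator with intact and double-meniscectomy
    variants, a ramp-hold body-weight creep protocol, closed-form poroelastic
    verification oracles, and reporting of contact areas, interface and
    compartment load partitions, peak compressive stress, fluid pressure and
    fluid load support ratios as tidy time series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    readr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
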