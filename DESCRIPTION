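Package: killisim
Title: Agent-Based Simulation of Cell Aggregation on a Spherical Shell
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates self-propelled embryonic cells confined between two
    concentric spherical layers, as in early annual killifish development.
    Cells carry a tangential polarity driven by rotational diffusion, contact
    inhibition of locomotion (CIL), and optional taxis toward an organizing
    center; they interact through a linear overlap adhesion/repulsion force
    and are held on the shell by confinement forces from the enveloping layer
    (EVL) and yolk syncytial layer (YSL). Positions follow overdamped implicit
    Euler dynamics and polarity angles follow an Euler-Maruyama scheme.
    Includes contact-graph cluster quantification, ensemble statistics,
    adhesion/CIL phase scans, trajectory input/output, plotting helpers, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
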