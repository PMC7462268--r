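Package: hbocsim
Title: Hemoglobin-Based Oxygen Carrier Enhanced Tumor Oxygenation Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Desk-scale simulator of oxygen transport in arterio-venous
    microvascular networks perfused by blood carrying both red-blood-cell
    hemoglobin and a plasma-phase hemoglobin-based oxygen carrier (HBOC).
    Provides Hill-model oxygen equilibrium curves and blood oxygen content,
    a seeded generator of synthetic tumor-bearing vascular networks on a
    lattice, Poiseuille network hemodynamics with empirical in-vivo
    viscosity, phase separation and shear-driven radius adaptation, a
    coupled vascular-tissue oxygen solver (axial pO2 ODE per segment,
    bisection mixing at nodes, nonlinear tissue diffusion with
    Michaelis-Menten consumption and vessel line sources), a Krogh tissue
    cylinder module for Sherwood-number calibration, top-load/exchange
    infusion scenarios for T-State and R-State polymerized hemoglobin with
    extraction-conserving boundary recalibration, and clinically analogous
    bulk oxygenation metrics (OEF decomposition, MRO2, hypoxic fractions,
    MVD/RBV/RBF).
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
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
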