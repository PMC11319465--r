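Package: dnawave
Title: Traveling-Wave Solutions of the Double-Chain DNA Model by a Fan
    Sub-Equation Expansion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Derives, evaluates and audits closed-form traveling-wave
    solutions of the coupled nonlinear equations describing longitudinal and
    transverse displacement differences of the two strands of a double-chain
    DNA molecule. Maps physical lattice parameters (membrane height, strand
    separation, rigidity, stress density, Young modulus, cross-section, mass
    density) to the reduced cubic-quadratic wave equation, performs the
    homogeneous-balance reduction and the sub-equation expansion in an
    auxiliary function obeying a general elliptic equation, implements the
    complete catalogue of auxiliary solutions (hyperbolic, trigonometric,
    rational-hyperbolic, Jacobi elliptic and Weierstrass families) with
    parameter-regime guards and singularity masking, and verifies every
    catalogued family against both the reduced ordinary differential equation
    and the governing partial differential equation, symbolically via an exact
    sparse polynomial engine and numerically via finite differences with
    convergence-order estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
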