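Package: oxydiff
Title: Oxygen Diffusion Measurement and Reaction-Diffusion Design for
    Cell-Laden Hydrogels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies oxygen transport in hydrogel slabs used for cell
    immobilization and encapsulation. Provides a one-dimensional transient
    layered-diffusion solver (Crank-Nicolson finite volumes) driven by a
    first-order-plus-dead-time gas boundary, estimation of oxygen diffusion
    coefficients from optode probe traces by mean-absolute-percent-error
    minimization, and a zero-order reaction-diffusion design framework
    (Thiele modulus, effectiveness factor, viable-front depth, and
    thickness-versus-cell-density design curves) for immobilized-cell
    systems such as alginate-encapsulated beta cells.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
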