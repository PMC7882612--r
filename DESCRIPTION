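Package: daisyfly
Title: Fly Colour Vision Modelling and Pollinator Mosaic Analysis for
    Daisy Communities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to analyse landscape-scale structuring of flower colour
    in annual daisy communities by their fly pollinators. Implements a
    categorical fly colour-opponency model (quantum catches under von
    Kries adaptation, detectability and discriminability in the 2-D
    opponency plane), site-level pollinator density computation with
    ordinary and Firth bias-reduced logistic regression of flower colour
    on fly density (robust to complete separation), generalized
    estimating equations with an exchangeable working correlation and
    jackknife variances for clustered binary flower-choice sequences,
    and synthetic generators for reflectance spectra, landscape surveys,
    and choice experiments so every stage runs without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
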