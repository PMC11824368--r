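Package: pathweaver
Title: Two-Field Generative Construction of Chemical Reaction Paths
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for generating initial guesses of chemical reaction paths
    from an initial state by integrating two vector fields: a
    transformation-guidance field (the unit tangent of the reaction path,
    oriented from reactant to product) and a denoising field (the vector
    from an off-path geometry back to the nearest point on the path).
    Provides exact field oracles computed from discretized reference paths,
    the Gaussian-mixture score theory linking the denoising field to Newton
    steps of the smoothed log-density, a stochastic tube sampler for
    training data, an E(3)-equivariant graph-attention field model and a
    dense baseline for low-dimensional toys, Gaussian negative-log-likelihood
    training losses with predicted per-atom uncertainty, conditional
    generation with classifier-free guidance and learned stopping, reaction
    bond/dihedral change detection, path-quality evaluation criteria, and
    synthetic fixture generators (2D multi-branch toy paths, n-alkane
    dihedral-rotation and bond-change paths).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
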