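Package: lnptools
Title: Characterization Analyses for Lignin Nanoparticles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analyses for colloidal lignin nanoparticle (LNP)
    characterization. Implements small-angle X-ray scattering (SAXS) analysis
    with a homogeneous-sphere/log-normal form-factor model, Guinier and Porod
    extrapolation, and the scattering invariant route to specific surface
    area; Flory-Huggins solvent screening from Hansen solubility parameters;
    geometric hydrogen-bond counting, radial distribution functions and
    solvent-accessible surface area on molecular configurations; Hertzian
    contact fits of AFM force-indentation curves; and particle-size
    statistics. A seeded synthetic-data generator produces every input the
    pipeline consumes with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    minpack.lm,
    pracma,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
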