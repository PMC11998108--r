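Package: mnswell
Title: Swelling, Absorption and Release Kinetics of Hydrogel-Forming
    Microneedles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis pipeline for suprachoroidal-space-inducing
    hydrogel-forming microneedle (HFMN) arrays. Provides parametric
    microneedle shape models with solid-of-revolution volume integration and
    depth-band volume-fraction scoring against the suprachoroidal space;
    pseudo-second-order swelling kinetics with gel characterization
    (equilibrium water content, gel fraction, solvent-displacement porosity);
    two-compartment drug-absorption transport parameters (permeability,
    partition and diffusion coefficients); ultra-fast drug-release kinetics
    with aliquot-replacement correction; and seeded synthetic-data
    generators that emulate each measurement process so every stage is
    testable without raw laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
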