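Package: gelsim
Title: Virtual Gelatin Model Construction and Validation Observables
Version: 0.1.0
Authors@R: person("Lukasz", "Kowalski", email = "lkowalski@example.org",
                  role = c("aut", "cre"))
Description: Builds an atomistic gelatin chain from a collagen alpha-1 sequence
    (hydroxyproline substitution and simulated trypsin digestion) and computes
    the observables used to validate molecular-dynamics models of dry gelatin:
    powder WAXS profiles via the Debye scattering equation with Cromer-Mann
    atomic form factors, probe-based (Connolly/accessible/van der Waals)
    occupied volume and fractional free volume, the Hansen solubility parameter
    from per-frame cohesive energy density, the isobaric thermal expansion
    coefficient from ln-density regression with a full ANOVA decomposition and
    confidence bands, glass-transition detection by continuous two-segment
    regression, and the Flory-Huggins/Flory-Rehner and Fujita free-volume
    application formulas. Includes seeded synthetic-data generators for every
    input class and a command-line interface over the pipeline stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
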