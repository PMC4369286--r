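Package: lferdesc
Title: Solute Descriptor Determination for Abraham Solvation Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines Abraham solvation-model solute descriptors (E, S, A,
    B, V, L) from measured saturation solubilities and water-solvent
    partition coefficients by over-determined linear least squares.
    Provides McGowan characteristic-volume calculation from molecular
    formula, fragment-based estimation of the excess molar refractivity
    including the monomer/dimer relation for carboxylic acids, curation of
    raw solubility data (unit conversion, Buchowski temperature correction,
    replicate averaging, Kamlet-Taft beta solvent classification), assembly
    and solution of the stacked partition/solubility equation system, and a
    replication driver for the trans-cinnamic acid monomer and dimer case
    study, together with a synthetic-data generator for parameter-recovery
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
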