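Package: sulfoflux
Title: Constraint-Based Analysis of Sulfolobus solfataricus Central Carbon Metabolism
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Flux balance analysis (FBA), optimal and suboptimal flux
    variability analysis (FVA), and minimization-of-metabolic-adjustment
    (MOMA) gene-deletion analysis for stoichiometric metabolic models,
    together with a curated central-carbon-metabolism model of the
    hyperthermoacidophilic archaeon Sulfolobus solfataricus, a biomass
    objective builder, growth-scenario pipelines (glucose, glucose with
    exopolysaccharide production, autotrophic bicarbonate fixation on
    sulfide, phenol, and a normalized carbon-source scan), per-pathway
    energy accounting, and a generator of random feasible stoichiometric
    networks with planted optima for solver validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    quadprog,
    xml2,
    yaml,
    jsonlite,
    stats,
    utils,
    methods,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
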