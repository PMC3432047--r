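#!/usr/bin/env Rscript
# Glucose growth with exopolysaccharide production: 22.5% of imported carbon
# leaves as EPS at the printed unit stoichiometry; growth and the
# biomass:CO2 ratio both drop.
suppressPackageStartupMessages(library(sulfoflux))
dir.create("results", showWarnings = FALSE)

model <- build_ccm_model()
eu <- ccm_eps_unit()
f <- compute_eps_flux(0.55, 0.225, eu$stoichiometry, eu$carbons)
message("EPS flux for 22.5% of imported carbon: ", round_half_up(f, 3),
        " mmol/gDW/h")
plain <- run_scenario(model, ccm_scenario("glucose"), fva = FALSE)
eps <- run_scenario(model, ccm_scenario("glucose_eps"), fva = FALSE)
print(plain); print(eps)
message("biomass with EPS is ",
        round(100 * eps$biomass_flux / plain$biomass_flux), "% of plain glucose; ",
        "biomass:CO2 carbon ratio falls from 1:",
        round(plain$co2_flux / plain$biomass_carbon, 1), " to 1:",
        round(eps$co2_flux / eps$biomass_carbon, 1))
write_scenario_report(eps, "results/glucose_eps")
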