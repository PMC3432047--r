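# Proxy biomass composition for the curated CCM fixture. The organism's
# measured biomass composition is not published (full-genome reconstructions
# borrow another archaeon's values); this file is a documented,
# precursor-level stand-in whose monomers draw on all major subsystems:
# amino-acid proxies (pyruvate/2-oxoglutarate/oxaloacetate families plus a
# lumped aromatic consuming erythrose 4-phosphate and PEP), a lumped
# nucleotide, glycogen/trehalose storage carbohydrate, a C40 isoprenoid
# lipid proxy, and an NADPH soluble pool. Molecular weights are residue
# weights (free monomer minus water) so consumed mass sums to ~1 g per gDW.
# GAM is the growth-associated maintenance in mmol ATP per gDW.
gam: 24.86
classes:
  protein:
    mass_fraction: 0.52
    monomers:
      - {id: ala, percent: 40, mw: 0.0711}
      - {id: glu, percent: 31, mw: 0.1291}
      - {id: asp, percent: 25, mw: 0.1151}
      - {id: aro, percent: 4, mw: 0.1620}
  rna_dna:
    mass_fraction: 0.16
    monomers:
      - {id: nuc, percent: 100, mw: 0.3220}
  carbohydrate:
    mass_fraction: 0.16
    monomers:
      - {id: glycogen, percent: 70, mw: 0.1621}
      - {id: tre, percent: 30, mw: 0.3423}
  lipid:
    mass_fraction: 0.13
    monomers:
      - {id: lipid, percent: 100, mw: 0.6500}
soluble:
  - {id: nadph, amount: 0.04, mw: 0.7454, byproducts: {nadp: 1}}
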