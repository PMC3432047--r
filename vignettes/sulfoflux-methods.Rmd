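---
title: "Constraint-based modelling of Sulfolobus solfataricus central carbon metabolism: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sulfoflux methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sulfoflux)
```

## The model and its assumptions

A metabolic model here is a stoichiometric matrix **S** (*m* metabolites ×
*n* reactions; a positive entry means the compound appears on the product
side) together with flux bounds. The central assumption is steady state:
internal metabolite concentrations are constant, so **S** *v* = 0, and the
cell is taken to have been optimized by evolution for growth, so flux
balance analysis (FBA) maximizes the biomass flux. Because *n* > *m* the
system is underdetermined: the optimum is one vertex among possibly many
alternative optimal flux distributions. Two consequences run through the
whole package:

* Flux variability analysis (FVA) characterizes the optimal (or
  near-optimal) set by separately minimizing and maximizing each flux with
  the biomass flux floored at a fraction of its optimum (1.0 = optimal FVA;
  0.95 is the suboptimal default, chosen because a 5 % tolerance already
  widens the admissible flux space substantially). Interval overlap between
  two scenarios is the significance criterion: only reactions whose
  intervals are disjoint can never assume the same flux in both conditions.
* Every analysis needing a single reference vector (MOMA, variability
  classification, scenario reports) uses the *parsimonious* FBA solution —
  the optimal vertex minimizing the total absolute flux — as a reproducible
  representative in which non-productive fluxes (those not contributing to
  biomass) vanish. Raw `solve_fba()` returns an arbitrary optimal vertex of
  the deterministic simplex and makes no such promise.

Knockouts are predicted with MOMA: mutants have not re-optimized, so the
perturbed network is assumed to stay as close as possible (Euclidean
distance) to the wild-type flux state. Gene associations use standard
semantics — OR joins isozymes, AND joins complex subunits; the logic source
never states its convention, and this is the field default. The scan
accepts an expressed-gene whitelist to emulate transcriptome filtering; by
default every gene is assumed expressed, which underestimates essentiality.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| P/O ratio | 0.5 | ATP per O reduced | archaeal SoxABCD/SoxEFGHIM terminal oxidases are inefficient; realized *structurally*: every lumped ETC reaction (NADH, NADPH, FADH₂ entry) yields 0.5 ATP per O atom, with no donor-specific distinction because none is documented |
| NGAM | 1.9 (growth scenarios), 0.67 (carbon scan) | mmol ATP gDW⁻¹ h⁻¹ | non-growth maintenance, an *equality-constrained* ATP-hydrolysis flux; each value calibrated to the observed 25 % carbon usage ratio on glucose |
| GAM | 24.86 | mmol ATP gDW⁻¹ | growth-associated maintenance, consumed inside the biomass reaction |
| glucose uptake | 0.55 | mmol gDW⁻¹ h⁻¹ | measured at 80 °C |
| HCO₃⁻ uptake | 3.3 | mmol gDW⁻¹ h⁻¹ | same carbon feed as 0.55 glucose |
| artificial bound | 100 000 | mmol gDW⁻¹ h⁻¹ | substituted for ±∞ at solve time only, keeping model files solver-agnostic; stoichiometrically balanced cycles show FVA widths clipped at this sentinel and are reported, not removed |
| EPS flux | 0.049 | mmol gDW⁻¹ h⁻¹ | routes 22.5 % of imported glucose carbon into EPS units of 1.2 glucose + 1 mannose + 0.18 N-sulfo-glucosamine + 0.13 galactose |
| ED branch energetics | GAPN catabolic | — | see below |

Energy equivalences used in per-pathway accounting: at P/O = 0.5, 2 NAD(P)H
≡ 1 ATP, and ferredoxin-NADP⁺ reductase makes 2 reduced ferredoxin ≡ 1
NAD(P)H. The `EnergyAccount` tracks NADH and FADH₂ separately from NAD(P)H
(the fixture distinguishes the pools) and folds them in at the same P/O
weight.

## The curated fixture

The fixture transcribes the organism's central carbon metabolism —
branched Entner–Doudoroff (ED) catabolism, gluconeogenesis, the reverse
ribulose-monophosphate (RuMP) pathway, TCA cycle with glyoxylate shunt and
anaplerosis, storage carbohydrates, sulfur metabolism, the
hydroxypropionate–hydroxybutyrate (HP/HB) CO₂-fixation cycle, phenol
degradation, and transport — into 196 reactions with full elemental carbon
bookkeeping (CoA-containing metabolites carry the complete CoA carbon so
every internal reaction balances). A manifest maps each numbered figure
enzyme to its reaction; promiscuous enzymes (glucose/galactose
dehydrogenase, the two ED aldolases, the two transketolase steps) share one
gene each.

Deliberate curation choices, in decreasing order of consequence:

* **Catabolic GAP oxidation uses the non-phosphorylating GAPN; the
  phosphorylating GAPDH + PGK pair is restricted to the gluconeogenic
  direction** (consistent with treating ATP-consuming reactions as
  irreversible). This is what makes the semi- and non-phosphorylative ED
  branches exactly energy-equivalent (0 net ATP + 1 NAD(P)H each per
  glucose-half) and hence mutually substitutable in optimal FVA, as
  observed for the organism. It also means that glycerol → pyruvate
  accounts as 0 ATP + 2 NAD(P)H + 2 FADH₂ per 2 glycerol (2
  ATP-equivalents) rather than +2 substrate-level ATP; the totals are
  identical at P/O = 0.5, only the carrier split differs.
* **Pentose provision through the reverse RuMP pathway releases one
  formaldehyde per pentose** (hexulose-6-phosphate synthase run backwards).
  The formaldehyde is oxidized to formate and reused as the C1 donor of the
  lumped nucleotide synthesis, so no carbon is silently destroyed. Without
  a transaldolase, the erythrose-4-phosphate demand of aromatic amino-acid
  synthesis forces an equimolar sedoheptulose-7-phosphate export — the leak
  carries 0.85 % of imported carbon on glucose, under the documented 3 %
  ceiling, and is completely inflexible in FVA.
* **HP/HB cycle ligases are ADP-forming** (one ATP-equivalent each), so one
  net acetyl-CoA from 2 HCO₃⁻ costs exactly 4 ATP (two carboxylases + two
  ligases). AMP-forming ligases would cost more than the documented total.
  The cycle's net NAD(P)H demand comes out at 4 (5 NADPH in, 1 NADH back),
  not the 3 sometimes quoted; summing the pathway's reductive steps cannot
  yield 3 and the discrepancy is left as documented.
* **Galactose catabolites are pooled with KDG**: the promiscuous ED enzymes
  process 2-keto-3-deoxy-galactonate and -gluconate as one species.
* **Pentose catabolism** defaults to the oxidative route to 2-oxoglutarate
  (2 NADPH per pentose); a lumped malate-route alternative ships disabled
  and can be switched on (`pentose_route = "malate"`), giving a visibly
  lower yield.
* Compartments are cytosol/external only, protons and charge are not
  balanced (there is no charge model at growth pH 2–4), and carbon is the
  only enforced elemental balance.

### The proxy biomass

The organism's full biomass composition is not published; the fixture ships
a documented precursor-level stand-in (`sso_biomass.yml`): amino-acid
proxies for the pyruvate/2-oxoglutarate/oxaloacetate families plus a lumped
aromatic (consuming erythrose 4-phosphate and PEP), a lumped nucleotide
with full synthesis costs (PRPP, C1, 6 ATP, 2 NADPH), glycogen + trehalose
storage, a C40 isoprenoid lipid proxy (24 acetyl-CoA, 24 ATP, 20 NADPH —
archaeal ether lipids are isoprenoid), and an NADPH soluble pool whose NADP
moiety returns to the pool. Molecular weights are residue weights, so
consumed mass sums to 1 g per gDW (residual 2 × 10⁻⁴ g) and the objective
flux is μ in h⁻¹. All fixture-based checks are ratio- or ordering-based:
absolute growth rates from a proxy biomass are not comparable to measured
ones, although the glucose scenario happens to land at μ = 0.0200 h⁻¹.

## Numerical choices

* LP solver: a bounded-variable two-phase revised primal simplex
  (deterministic; Dantzig pricing with automatic Bland's-rule fallback
  against degenerate cycling; feasibility tolerance 10⁻⁹ scaled, equality
  comparisons at 10⁻⁶ — fluxes span 10⁻² to 10⁵ given the sentinels).
  FVA warm-starts each of its 2*n* subproblems from the previous optimal
  basis. An independent brute-force oracle (exhaustive vertex enumeration
  with dense QR solves, guarded to ≤ 12 reactions) validates FVA on
  generated networks, and `quadprog`'s dual active-set method solves MOMA
  (the rank-deficient rows of **S** from conserved cofactor moieties are
  reduced to an independent basis first).
* FVA at fraction 1.0 backs the biomass floor off by 10⁻⁹·max(1, |opt|) so
  the fixed-optimum problem stays feasible against simplex round-off; tiny
  interval inversions are clamped.
* Printed-value comparisons round half-up to the printed number of
  decimals (`round_half_up()`).
* Degenerate inputs: an empty model yields a 0 × 0 matrix; exchange
  reactions must touch exactly one metabolite; knockouts of zero-flux
  reactions return the wild type at distance 0; infeasible scenarios are
  reported as such rather than erroring.

## What the synthetic generator does and does not emulate

`generate_random_model()` composes flux-carrying paths — a bottlenecked
uptake, a linear backbone, an objective sink, plus random one-to-one
internal conversions — so the planted vector satisfies **S** *v* = 0 by
construction and the planted throughput is provably the FBA optimum
(1:1 stoichiometry conserves molecule count; the uptake is the unique
bottleneck). Seeds are mandatory and fully determine the output. The
generator validates solver correctness (oracle equivalence, planted-optimum
recovery, MOMA identity) but does not imitate genome-scale degree
distributions, cofactor coupling, or realistic redundancy; passing those
tests certifies the mathematics, not biological realism.

## Known limitations

* The fixture is central carbon metabolism only (no purine/pyrimidine,
  amino-acid, lipid or coenzyme biosynthesis subsystems beyond the lumped
  proxies), so knockout fractions, carbon usage ratios and absolute growth
  rates are fixture-specific; only orderings and qualitative contrasts are
  meaningful. The headline full-genome quantities (0.0222 h⁻¹ on glucose,
  18 % lethal deletions, 83 % fixed reactions) depend on a 718-reaction
  reconstruction that is not reproducible at this scale.
* Doubling GAM at fixed glucose lowers biomass by 20.3 % here. A linear
  budget argument (uptake × ATP-per-carbon = NGAM + μ × per-gram cost)
  shows any central-carbon model with these uptake/NGAM settings must land
  near 20–25 %; substantially smaller sensitivities require per-gram costs
  several times larger than the fixture's ≈ 98 mmol ATP-eq gDW⁻¹, i.e. a
  full biosynthetic network.
* Glucose-vs-phenol comparison: the fixture calls the TCA segment
  significantly different as well as the ED pathway, because phenol feeds
  all of its carbon in at acetyl-CoA/pyruvate and the small network has no
  slack to absorb the higher TCA throughput; in the full-genome setting
  most TCA fluxes overlap. The directional findings (ED shut down, enolase
  reversed to gluconeogenic, phosphoenolpyruvate carboxykinase essential
  for gluconeogenesis) are reproduced.
* Regulation is absent: the glyoxylate shunt is catabolite-repressed in
  vivo but freely usable here, and the all-genes-expressed assumption makes
  essentiality an underestimate.
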