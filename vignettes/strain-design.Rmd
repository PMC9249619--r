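---
title: "Designing flux-forced overproducer strains with fluxforce"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing flux-forced overproducer strains with fluxforce}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxforce)
```

## The design problem

A heterologous production pathway competes with growth for precursors.
The case built into this package is *para*-aminophenylalanine (pAF)
production in *Escherichia coli*: the PapA/PapB/PapC enzymes convert
chorismate — the branch-point product of the shikimate pathway — into
4-aminophenylpyruvate, which host aminotransferases transaminate to pAF.
Chorismate and glutamine also feed biomass and the aromatic amino acids,
so every mole of pAF is a mole not spent on growth. The engineering
question is: which *minimal* set of flux interventions (upregulations,
downregulations, knockouts) in the host's native metabolism guarantees
substantial pAF formation even in the worst case, while the cell still
grows?

`fluxforce` answers it with constraint-based modeling. A genome-scale
model (GEM) is a stoichiometric matrix $S$ with flux bounds
$l \le v \le u$; any steady-state flux distribution satisfies $S v = 0$.
Flux balance analysis (FBA) optimizes one flux over that polytope; flux
variability analysis (FVA) reports each reaction's attainable interval.

## The MUST/FORCE procedure

The strain-design core follows the classic push–pull logic:

1. **Wild-type space.** `wildtype_ranges()` runs FVA on the reference
   strain under measured flux intervals (`read_flux_data()`), plus an
   optional growth floor expressed as a fraction of the maximum growth
   attainable under those data. The floor stands in for the near-optimal
   growth of an evolved reference when few fluxes were measured.
2. **Overproducer space.** `overproducer_ranges()` runs FVA on the
   grafted model under two requirements: growth at least
   $g \cdot \mu_{\max}$ and product at least $p \cdot P_{\max}$, where
   $P_{\max}$ is the theoretical maximum product flux. Defaults are
   $g = 0.2$ and $p = 0.8$.
3. **Superimposition.** `classify_must_sets()` compares the two interval
   maps reaction by reaction with margin $\varepsilon$ (default $10^{-3}$
   flux units, deliberately coarser than the $10^{-6}$ LP tolerance):
   MUST-U when the overproducer minimum exceeds the wild-type maximum,
   MUST-L when the overproducer maximum falls below the wild-type
   minimum, MUST-X when the overproducer range collapses onto zero while
   the wild-type range does not.
4. **Candidates.** Each MUST entry becomes one bound intervention. The
   imposed level is the overproducer-range boundary (the minimum for
   upregulations, the maximum for downregulations): it is the weakest
   bound consistent with every overproducing state, it is computable
   without further optimization, and it is logged so users can override
   it. Exclusions: reactions with no gene association cannot be
   addressed genetically; knockouts touching essential genes are
   removed when an essentiality scan is supplied; the grafted pathway
   itself can be excluded to force interventions into native metabolism
   (the "push" re-run).
5. **FORCE search.** `find_force_sets()` scores subsets of candidates by
   the *worst-case minimum product*: the LP minimum of product flux with
   the interventions applied and the growth floor active — the network
   "fighting back". The growth floor always references the
   pre-intervention maximum growth, so scores are comparable across
   subsets. Search is exhaustive subset enumeration in deterministic
   order (size, then lexicographic member label) with monotone pruning:
   because shrinking the feasible region can only raise an LP minimum,
   worst-case values are monotone under set inclusion, and supersets of
   a subset that already achieves the product target need no evaluation.
   On the candidate lists that survive MUST filtering (a handful of
   branch-point reactions) enumeration is exact and verifiable; a
   duality-based bilevel reformulation would only be needed for much
   larger candidate pools and is left as an extension point.

`reaction_to_gene_interventions()` translates reaction interventions to
gene interventions through the Boolean gene–protein–reaction (GPR)
rules: removing flux from an OR of isozymes requires hitting every
branch, an AND complex falls with any one subunit, and an upregulation
needs one minimal satisfying clause. This is why intervention counts
inflate from reactions to genes — chorismate mutase, carried by the
pheA/tyrA isozyme pair, costs two knockouts.

Gene-level downregulation is modeled by covering the mapped gene set and
then applying the *reaction-level bound*, not by deleting the genes in
the GPR sense. Full deletion of pheA and tyrA would also remove the
prephenate steps and make minimal-medium growth infeasible in the model;
experimentally the same problem is solved by supplementing the medium
with the aromatic amino acids. Knockout semantics remain available for
MUST-X entries, where they are exact.

## The grafted papBAC block

`builtin_papbac_pathway()` ships the consolidated four-step block plus
export machinery, in BiGG identifiers: PapA (chorismate + glutamine →
4-amino-4-deoxychorismate + glutamate, the aminodeoxychorismate-synthase
stoichiometry), PapB (isomerization to 4-amino-4-deoxyprephenate), PapC
(NAD⁺-dependent oxidative decarboxylation to 4-aminophenylpyruvate; the
cofactor follows the host prephenate-dehydrogenase analogy and is
recorded in the per-reaction provenance notes, overridable through the
YAML pathway format), an explicit glutamate-driven transamination to pAF
(the host enzymes are promiscuous and no single reaction id can be
pinned down, so the step is explicit with a configurable GPR), passive
export and an exchange. Every reaction balances C, N, H, O and charge
against the shipped formulas; net: one chorismate + one glutamine in,
one pAF + one CO₂ out, with the glutamate/2-oxoglutarate pair recycled.
`graft_pathway()` adds the block to a host without touching host
reactions; with the branch closed the host optimum is reproduced exactly
(graft neutrality).

## Linear programming

All analyses reduce to LPs of the form "optimize one flux subject to
$S v = 0$ and box bounds". Two interchangeable backends satisfy the
solver contract:

* `"simplex"` — a bounded-variable two-phase primal simplex written in
  R (dense; Dantzig pricing with a Bland anti-cycling fallback). It is
  the default for models up to a few hundred reactions and is itself
  validated against the exact oracle below.
* `"highs"` — the HiGHS interior-point/simplex code reached through
  scipy, driven as a batch subprocess so that a whole FVA or subset scan
  costs one process invocation. It is the default for genome-scale
  models.

Numerical conventions: feasibility/optimality tolerance $10^{-6}$;
reported fluxes with magnitude below $10^{-6}$ are printed as zero;
"unbounded" is an explicit status, never a large number. Yield is made
well defined under degenerate optima by a second LP that minimizes
substrate uptake at the fixed product optimum; a yield with zero uptake
is an error rather than an infinity. Infeasible FVA systems are
diagnosed by constraint-relaxation probing: each extra constraint is
dropped in turn and the ones whose removal restores feasibility are
named.

`brute_force_oracle()` is the package's independent referee: it
enumerates every basic feasible solution of the polytope in exact
rational arithmetic (numerator/denominator pairs with gcd reduction and
an overflow guard), so its optimum carries no floating-point error. It
is guarded to models of at most 12 reactions and requires finite bounds,
which every toy satisfies. A numeric prefilter skips clearly infeasible
vertices before exact evaluation; the exact check remains the arbiter
near boundaries.

## The toy generator and what it does (not) show

`generate_toy_model()` emulates the chorismate node in miniature:
substrate exchange → transport → supply into a hub metabolite; the hub
feeds $k_b$ biomass-coupled branches (biomass consumes one unit from
each; every amino acid also has a free demand sink), $k_f$ free overflow
branches (demand-drained, the structural "place to hide" flux that makes
an overflow knockout necessary — the enterochelin role), and a product
branch. With inverse-yield sum $q = \sum_i 1/y_i$, uptake bound $U$ and
product yield $y_p$, the closed forms are: maximum growth $U/q$,
theoretical maximum product $y_p U$, envelope upper boundary
$y_p (U - q b)$. Under the default thresholds $g + p = 1$, the
overproducer state is fully pinned and the unique minimal FORCE set is
\{up supply at $U$; down each biomass branch at $g U / (q y_i)$; knock
out each free branch\} with worst-case minimum $p\, y_p U$. The demand
sinks are essential to that uniqueness: without them the biomass
coupling would cap all branches as soon as one is capped, and a smaller
set would suffice.

The wild-type fixture pins the measured substrate uptake at $0.8 U$
(below the bound, so the supply step is genuinely classifiable as
MUST-U) and the wild-type FVA uses a 0.9 growth floor, standing in for
a densely measured central metabolism. The canonical fixture
`toy_chor_model()` instantiates this with $U = 10$, two unit-yield
biomass branches carrying the GPRs `trpA1 and trpA2` / `pheA or tyrA`,
one overflow branch (`entA`), and a unit-yield product branch: maximum
growth 5, theoretical maximum product 10, worst-case minimum 8 (80%)
for the quadruple intervention set, gene-level cost 5.

Thresholds may be perturbed without changing the identified intervention
*identities* as long as they stay on the saturating line $g + p = 1$,
where the overproducer state remains pinned; the imposed levels move
with $g$. Off that line the overflow branch regains slack and drops out
of MUST-X — the toy's sharp all-or-nothing epistasis is a deliberate
idealization.

Toys deliberately omit cofactor balancing, compartments beyond
cytosol/extracellular, and alternative routes. Passing the recovery
battery therefore demonstrates the correctness of the pipeline's logic
(ranges, classification, search, gene mapping), not predictive fidelity
on real metabolism; the genome-scale checks below address the latter.

## Genome-scale behavior and known limitations

On the BiGG iJO1366 reconstruction under aerobic M9 glucose (shipped
preset `m9_aerobic_glucose`; glucose uptake 10 mmol/gDW/h, the community
convention — every reported quantity is a per-glucose ratio or
percentage and is invariant to this choice, a property the test suite
asserts), the grafted model's theoretical pAF yield computes to 0.5536
mol/mol, the growth-constrained maximum at a 20% growth floor to 44.4
per 100 mol glucose (80.1% of theoretical), and adding the
enterochelin-branch knockout to the three push–pull interventions lifts
the worst-case minimum from 64.6% to 79.7% of theoretical maximum.
The three-intervention minimum is the one quantity sensitive to inputs
this package must synthesize: it depends on how much flux the
isochorismate/enterochelin and related drains can absorb, which in turn
depends on the wild-type flux dataset and the exact imposed levels.
With a measured central-metabolism flux table (the intended input of
`wildtype_ranges()`; `inst/extdata/toy_flux_data.tsv` shows the format)
the classification tightens and the value drops; the
pipeline reports its achieved value alongside the run manifest so the
comparison is explicit.

Stoichiometric models carry no regulation: allosteric feedback in the
shikimate pathway (AroF/G/H inhibition, TyrR repression) is invisible
here, and interventions that act through such feedback cannot be
predicted by this machinery. Second-order MUST pairs, OptKnock-style
bilevel MILP variants, parsimonious FBA, loopless FVA and thermodynamic
constraints are out of scope.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` size their experiments to run
on one CPU in a few minutes: 100 seeded toys for full-pipeline recovery
(60 in the script), oracle cross-checks on the canonical fixture plus
10 generated toys (every one within the 12-reaction guard), 11-point
envelopes, and a handful of genome-scale LPs on iJO1366 through the
HiGHS backend. These sizes are choices, not limits of the method; all
of them scale by changing one argument.
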