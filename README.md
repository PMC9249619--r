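# fluxforce

Strain design by flux forcing in genome-scale metabolic models.

`fluxforce` is an R toolkit for a recurring metabolic-engineering
question: after grafting a heterologous production pathway into a host's
genome-scale model (GEM), which **minimal set of flux interventions**
(upregulations, downregulations, knockouts) in the native network
guarantees a high **worst-case minimum** product formation while the
strain keeps growing?

The built-in application is *para*-aminophenylalanine (pAF) production
in *Escherichia coli*: the papBAC enzyme block converts chorismate — the
shikimate-pathway branch point that also feeds phenylalanine, tyrosine,
tryptophan and enterochelin — into 4-aminophenylpyruvate, which native
aminotransferases convert to pAF. Everything else is pathway- and
host-agnostic.

## The method

For a stoichiometric matrix $S$ with flux bounds $l \le v \le u$, all
analyses are linear programs over the steady-state polytope
$\{v : S v = 0,\ l \le v \le u\}$:

* **FBA / FVA** — optimize one flux; or bracket every reaction's
  attainable interval.
* **MUST classification** — superimpose the wild-type flux ranges
  (FVA under measured flux data) and the overproducer ranges (FVA under
  growth $\ge g\,\mu_{\max}$ and product $\ge p\,P_{\max}$; defaults
  $g=0.2$, $p=0.8$). Reactions whose flux must increase (MUST-U),
  decrease (MUST-L) or vanish (MUST-X) in any overproducing state become
  candidate interventions.
* **FORCE search** — enumerate candidate subsets (deterministic order,
  monotone pruning) and score each by the worst-case minimum product:
  the LP *minimum* of product flux under the imposed interventions and a
  growth floor — the network "fighting back".
* **GPR mapping** — translate reaction interventions into minimal gene
  sets through the Boolean gene–protein–reaction rules (isozymes: hit
  every branch; complexes: any subunit), plus combinatorial epistasis
  scans at reaction and gene level.

Two interchangeable LP backends satisfy one solver contract: a pure-R
bounded-variable simplex (default for small models; validated against an
exact rational vertex-enumeration oracle) and HiGHS via a batched
`python`/scipy bridge (default for genome-scale models).

## Worked example

The canonical toy fixture mimics the chorismate node: substrate →
hub; branches to trp-like and phe-like sinks (feeding biomass), an
enterochelin-like overflow, and a graftable product branch.

```r
library(fluxforce)

m <- toy_chor_model()
fba(m)$objective_value                      # max growth: 5
theoretical_max_yield(m, "EX_paf", "EX_glc")$yield   # 1 mol/mol

pl <- toy_pipeline(m)                       # ranges -> MUST -> FORCE
pl$candidates
#>   reaction_id kind level
#> 1      R_chor   up    10
#> 2       R_ent   ko    NA
#> 3       R_phe down     1
#> 4       R_trp down     1
pl$force[pl$force$minimal, c("members", "size", "worst_case_min_product", "percent_of_max")]
#>                                    members size worst_case_min_product percent_of_max
#> 1 down:R_phe,down:R_trp,ko:R_ent,up:R_chor    4                      8             80
```

The unique minimal FORCE set pushes flux into the hub (upregulate the
supply step), caps both amino-acid drains, and deletes the overflow
branch; any proper subset leaves an escape route and forces nothing
(worst-case minimum 0) — the all-or-nothing epistasis that makes the
combinatorial analysis necessary. Mapping to genes costs 5 genes for 4
reactions because the phe-branch is carried by an isozyme pair
(`pheA or tyrA`).

For a genome-scale run, point the pipeline at an iJO1366 SBML file
(`find_ijo1366()` locates a local copy, e.g. the one bundled with the
cobra Python toolbox):

```r
host  <- read_sbml(find_ijo1366())
model <- graft_pathway(host, builtin_papbac_pathway())
model <- apply_medium(model, read_medium("m9_aerobic_glucose"))
theoretical_max_yield(model, "EX_paf_e", "EX_glc__D_e", solver = "highs")$yield
#> [1] 0.5536126     # mol pAF per mol glucose, zero-growth maximum
```

`run_pipeline(run_config(...))` drives the whole sequence and writes TSV
tables, a JSON summary and a YAML manifest;
`inst/scripts/fluxforce-cli.R` wraps it for shell use.

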