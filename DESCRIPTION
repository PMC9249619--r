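Package: fluxforce
Title: Strain Design by Flux Forcing in Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based strain design for heterologous pathway
    overproduction. Reads genome-scale metabolic models (SBML Level 3 with
    the FBC package, and the community JSON dialect), grafts a heterologous
    biosynthesis pathway (the built-in papBAC block converting chorismate to
    para-aminophenylalanine), and identifies minimal sets of flux
    interventions (upregulations, downregulations, knockouts) that maximize
    the worst-case minimum product formation while preserving a required
    growth rate. Provides flux balance and flux variability analysis behind
    a pluggable linear-programming backend, production envelopes, MUST-set
    classification by superimposition of wild-type and overproducer flux
    ranges, exhaustive FORCE-set search with monotone pruning, mapping of
    reaction interventions to gene interventions through gene-protein-
    reaction rules, a combinatorial epistasis scan, and a generator of toy
    branch-point models with analytically known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    xml2,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
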