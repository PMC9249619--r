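# Toy product branch as a user-editable pathway file (mirrors the built-in
# branch of the canonical toy fixture).
product_exchange: EX_paf
metabolites:
  - {id: paf_e, name: product, compartment: e}
reactions:
  - {id: R_pap, equation: "chor_c -> paf_e", lower: 0, upper: 1000, gpr: papA, note: toy product branch}
  - {id: EX_paf, equation: "paf_e ->", lower: 0, upper: 1000, note: product exchange}
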