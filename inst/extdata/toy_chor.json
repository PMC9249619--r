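{
  "id": "toy_chor_v1",
  "metabolites": [
    {
      "id": "glc_e",
      "name": "glucose",
      "compartment": "e"
    },
    {
      "id": "glc_c",
      "name": "glucose",
      "compartment": "c"
    },
    {
      "id": "chor_c",
      "name": "chorismate-like hub",
      "compartment": "c"
    },
    {
      "id": "trp_c",
      "name": "tryptophan-like",
      "compartment": "c"
    },
    {
      "id": "phe_c",
      "name": "phenylalanine-like",
      "compartment": "c"
    },
    {
      "id": "ent_c",
      "name": "enterochelin-like",
      "compartment": "c"
    },
    {
      "id": "paf_e",
      "name": "product",
      "compartment": "e"
    }
  ],
  "reactions": [
    {
      "id": "EX_glc",
      "name": "glucose exchange",
      "metabolites": {
        "glc_e": -1
      },
      "lower_bound": -10,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "objective_coefficient": 0
    },
    {
      "id": "T_glc",
      "name": "glucose transport",
      "metabolites": {
        "glc_e": -1,
        "glc_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "objective_coefficient": 0
    },
    {
      "id": "R_chor",
      "name": "hub supply",
      "metabolites": {
        "glc_c": -1,
        "chor_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "aroT",
      "objective_coefficient": 0
    },
    {
      "id": "R_trp",
      "name": "trp branch",
      "metabolites": {
        "chor_c": -1,
        "trp_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "trpA1 and trpA2",
      "objective_coefficient": 0
    },
    {
      "id": "DM_trp",
      "name": "trp demand",
      "metabolites": {
        "trp_c": -1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "objective_coefficient": 0
    },
    {
      "id": "R_phe",
      "name": "phe branch",
      "metabolites": {
        "chor_c": -1,
        "phe_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "pheA or tyrA",
      "objective_coefficient": 0
    },
    {
      "id": "DM_phe",
      "name": "phe demand",
      "metabolites": {
        "phe_c": -1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "objective_coefficient": 0
    },
    {
      "id": "R_ent",
      "name": "ent overflow branch",
      "metabolites": {
        "chor_c": -1,
        "ent_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "entA",
      "objective_coefficient": 0
    },
    {
      "id": "DM_ent",
      "name": "ent demand",
      "metabolites": {
        "ent_c": -1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "objective_coefficient": 0
    },
    {
      "id": "BIOMASS",
      "name": "biomass",
      "metabolites": {
        "trp_c": -1,
        "phe_c": -1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "objective_coefficient": 1
    },
    {
      "id": "R_pap",
      "name": "product branch",
      "metabolites": {
        "chor_c": -1,
        "paf_e": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "papA",
      "objective_coefficient": 0
    },
    {
      "id": "EX_paf",
      "name": "product exchange",
      "metabolites": {
        "paf_e": -1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "objective_coefficient": 0
    }
  ],
  "genes": [
    {
      "id": "aroT",
      "name": "aroT"
    },
    {
      "id": "entA",
      "name": "entA"
    },
    {
      "id": "papA",
      "name": "papA"
    },
    {
      "id": "pheA",
      "name": "pheA"
    },
    {
      "id": "trpA1",
      "name": "trpA1"
    },
    {
      "id": "trpA2",
      "name": "trpA2"
    },
    {
      "id": "tyrA",
      "name": "tyrA"
    }
  ]
}
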