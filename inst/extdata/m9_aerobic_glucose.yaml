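# Aerobic minimal M9 medium with glucose as sole carbon source, in BiGG
# exchange-reaction ids. Uptake rates in mmol/gDW/h: glucose capped at the
# community-standard 10, inorganic ions effectively unconstrained, vitamin
# B12 trace-level. Unlisted exchanges are closed for uptake by
# apply_medium() (secretion stays open).
uptake:
  EX_glc__D_e: 10
  EX_o2_e: 1000
  EX_nh4_e: 1000
  EX_pi_e: 1000
  EX_so4_e: 1000
  EX_h2o_e: 1000
  EX_h_e: 1000
  EX_co2_e: 1000
  EX_k_e: 1000
  EX_na1_e: 1000
  EX_cl_e: 1000
  EX_ca2_e: 1000
  EX_mg2_e: 1000
  EX_fe2_e: 1000
  EX_fe3_e: 1000
  EX_cu2_e: 1000
  EX_mn2_e: 1000
  EX_zn2_e: 1000
  EX_cobalt2_e: 1000
  EX_mobd_e: 1000
  EX_ni2_e: 1000
  EX_sel_e: 1000
  EX_slnt_e: 1000
  EX_tungs_e: 1000
  EX_cbl1_e: 0.01
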