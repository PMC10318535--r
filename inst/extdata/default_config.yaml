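params:
  V_C: 5.0
  V_P: 60.0
  V_LN: 0.0005
  rho_cell: 1.0e+09
  f_int: 0.55
  C_seed: 1000000.0
  d_0: 5.0
  C_max: 1.0e+12
  k_growth: 0.012
  k_apop: 0.001
  k_kill: 0.12
  K_ratio: 0.1
  n_ratio: 1.0
  a_neo: 1.0e-18
  a_self: 5.0e-18
  k_P_deg: 1.0
  k_up: 1.0e-07
  APC_base: 100000.0
  k_APC0: 0.1
  k_mat: 1.0
  K_P: 1.0e-11
  k_mAPC_mig: 0.2
  k_APC_death: 0.02
  k_nT_source: 8.0e+07
  k_nT_death: 0.01
  k_CP: 0.1
  k_PC: 0.05
  k_CLN: 0.002
  k_LNC: 0.2
  k_act: 4.0
  K_act: 20000.0
  n_act: 2.0
  TCC: 80.0
  TCC_ref: 100.0
  k_aT_prolif: 0.3
  aT_max: 5.0e+09
  k_aT_exit: 0.5
  f_Treg: 0.15
  k_Teff_death_C: 0.05
  k_Teff_death_T: 0.1
  k_infil: 0.12
  K_C_inf: 5.0e+10
  k_exh_PD1: 0.1
  k_exh_Treg: 0.1
  K_Treg_exh: 5000000.0
  k_Texh_death: 0.05
  k_ThTreg: 0.1
  K_TGFb: 1.0e-11
  K_ArgI_td: 1.0e-08
  K_ArgI: 5.0e-08
  K_NO: 1.0e-07
  K_Treg_supp: 5000000.0
  K_PD1: 1.15
  n_PD1: 4.0
  k_MDSC_rec: 50000.0
  K_CCL2: 1.0e-10
  MDSC_max: 1.0e+08
  k_MDSC_death: 0.05
  k_CCL2_sec: 5.0e-21
  k_CCL2_deg: 2.0
  k_ArgI_sec: 5.0e-18
  k_ArgI_deg: 5.0
  k_NO_sec: 1.0e-17
  k_NO_deg: 10.0
  k_TGFb_sec: 1.0e-19
  k_TGFb_deg: 5.0
  CL_A: 0.026
  k_CP_A: 0.25
  k_PC_A: 0.35
  k_CT_A: 4.0e-06
  k_TC_A: 0.1
  k_TLN_A: 0.01
  k_LNC_A: 1.0
  MW_A: 145000.0
  CL_E: 0.35
  k_CP_E: 0.25
  k_PC_E: 0.35
  k_CT_E: 4.0e-06
  k_TC_E: 0.1
  k_TLN_E: 0.01
  k_LNC_E: 1.0
  MW_E: 195000.0
  Kd_CD3: 1.0e-07
  Kd_CEA: 3.0e-08
  chi: 10.0
  CD3_per_T: 100000.0
  CEA_per_C: 300000.0
  Kd_PD1_PDL1: 5.0e-07
  Kd_A_PDL1: 4.0e-10
  PD1_per_T: 10000.0
  PDL1_per_C: 50000.0
  PDL1_per_Treg: 20000.0
  f_syn: 0.001
  K_syn: 30.0
  n_syn: 1.5
  beta_max: 10.5
  beta_prolif: 0.3
  use_kill_boost: 1.0
  use_prolif_boost: 1.0
  decoy: 0.5
units:
  V_C: L
  V_P: L
  V_LN: L
  rho_cell: cells/cm^3
  f_int: '1'
  C_seed: cells
  d_0: cm
  C_max: cells
  k_growth: 1/day
  k_apop: 1/day
  k_kill: 1/day
  K_ratio: '1'
  n_ratio: '1'
  a_neo: mol/cell
  a_self: mol/cell
  k_P_deg: 1/day
  k_up: 1/cell/day
  APC_base: cells
  k_APC0: 1/day
  k_mat: 1/day
  K_P: mol
  k_mAPC_mig: 1/day
  k_APC_death: 1/day
  k_nT_source: cells/day
  k_nT_death: 1/day
  k_CP: 1/day
  k_PC: 1/day
  k_CLN: 1/day
  k_LNC: 1/day
  k_act: 1/day
  K_act: cells
  n_act: '1'
  TCC: '1'
  TCC_ref: '1'
  k_aT_prolif: 1/day
  aT_max: cells
  k_aT_exit: 1/day
  f_Treg: '1'
  k_Teff_death_C: 1/day
  k_Teff_death_T: 1/day
  k_infil: 1/day
  K_C_inf: cells
  k_exh_PD1: 1/day
  k_exh_Treg: 1/day
  K_Treg_exh: cells
  k_Texh_death: 1/day
  k_ThTreg: 1/day
  K_TGFb: M
  K_ArgI_td: M
  K_ArgI: M
  K_NO: M
  K_Treg_supp: cells
  K_PD1: '1'
  n_PD1: '1'
  k_MDSC_rec: cells/day
  K_CCL2: M
  MDSC_max: cells
  k_MDSC_death: 1/day
  k_CCL2_sec: mol/cell/day
  k_CCL2_deg: 1/day
  k_ArgI_sec: mol/cell/day
  k_ArgI_deg: 1/day
  k_NO_sec: mol/cell/day
  k_NO_deg: 1/day
  k_TGFb_sec: mol/cell/day
  k_TGFb_deg: 1/day
  CL_A: 1/day
  k_CP_A: 1/day
  k_PC_A: 1/day
  k_CT_A: 1/day/cm^3
  k_TC_A: 1/day
  k_TLN_A: 1/day
  k_LNC_A: 1/day
  MW_A: g/mol
  CL_E: 1/day
  k_CP_E: 1/day
  k_PC_E: 1/day
  k_CT_E: 1/day/cm^3
  k_TC_E: 1/day
  k_TLN_E: 1/day
  k_LNC_E: 1/day
  MW_E: g/mol
  Kd_CD3: M
  Kd_CEA: M
  chi: '1'
  CD3_per_T: receptors/cell
  CEA_per_C: receptors/cell
  Kd_PD1_PDL1: M
  Kd_A_PDL1: M
  PD1_per_T: receptors/cell
  PDL1_per_C: receptors/cell
  PDL1_per_Treg: receptors/cell
  f_syn: '1'
  K_syn: synapses/cell
  n_syn: '1'
  beta_max: '1'
  beta_prolif: '1'
  use_kill_boost: flag
  use_prolif_boost: flag
  decoy: '1'
ranges:
- name: d_0
  lower: 2.0
  upper: 8.0
  scale: linear
  provenance: literature
- name: k_growth
  lower: 0.005
  upper: 0.025
  scale: log
  provenance: literature
- name: TCC
  lower: 10.0
  upper: 1000.0
  scale: log
  provenance: calibrated
- name: k_kill
  lower: 0.05
  upper: 3.0
  scale: log
  provenance: calibrated
- name: CEA_per_C
  lower: 10000.0
  upper: 1000000.0
  scale: log
  provenance: literature
- name: PDL1_per_C
  lower: 5000.0
  upper: 500000.0
  scale: log
  provenance: literature
- name: k_nT_source
  lower: 3.0e+07
  upper: 2.0e+08
  scale: log
  provenance: literature
- name: k_exh_Treg
  lower: 0.02
  upper: 0.5
  scale: log
  provenance: calibrated
- name: k_MDSC_rec
  lower: 10000.0
  upper: 1000000.0
  scale: log
  provenance: literature
- name: decoy
  lower: 0.0
  upper: 1.0
  scale: linear
  provenance: literature
screens:
  blood_T:
  - 300000.0
  - 5000000.0
  teff_treg:
  - 0.1
  - 50.0
  d_tol: 0.01
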