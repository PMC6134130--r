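v_mb: 0.409676
d_mb: 0.204838
k_pb: 0.409676
d_pb: 0.204838
v_mp: 0.573547
K_bp: 2.0
n_bp: 4.0
c_glu: 1.41811
K_gp: 7.58945
n_gp: 4.0
d_mp: 0.204838
k_pp: 0.181203
d_pp: 0.236352
v_mc: 0.819353
K_bc: 2.0
n_bc: 4.0
d_mc: 0.204838
k_pcr: 0.307257
d_pcr: 0.189081
k_ass: 0.236352
k_dis: 0.0590879
d_cp: 0.110297
K_pc: 1.0
n_pc: 6.0
v_mr: 11.66
K_br: 2.0
n_br: 6.0
d_mr: 0.14575
cneur: 1.4336
k_pr: 0.014575
d_pr: 0.14575
K_rb: 2.0
n_rb: 10.0
v_gb: 2.83339
k_fg: 11.300000000000001
d_g: 0.321479
k_gi: 0.824824
k_i: 2.0
K_ig: 7.58945
n_ig: 4.0
K_ie: 1.26491
n_ie: 4.0
d_i: 0.5
v_me: 0.399445
K_be: 2.0
n_be: 4.0
d_me: 0.199723
k_pe: 0.199723
d_pe: 0.199723
k_fa: 3.0
k_fo: 0.5
scn_peak: 6.0
food_edge: 0.25
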