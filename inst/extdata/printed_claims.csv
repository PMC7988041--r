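claim,printed,digits,category
ventricular_volume_ratio,13.9,1,hard
brain_volume_reduction_pct,17.4,1,hard
sas_volume_increase_pct,2.4,1,hard
sas_pressure_ratio_BC_A,5.5,1,hard
sas_pressure_ratio_BC_B,5.1,1,hard
sas_pressure_ratio_BC_C,5.1,1,hard
ca_pressure_ratio_BC_A,5.7,1,hard
ca_pressure_ratio_BC_B,5.3,1,hard
ca_pressure_ratio_BC_C,5.2,1,hard
reynolds_group_diff_BC_A_pct,16.9,1,hard
reynolds_group_diff_BC_B_pct,15.8,1,hard
reynolds_group_diff_BC_C_pct,15.7,1,hard
icp_agreement_BC_A_pct,36.2,1,borderline
icp_agreement_BC_B_pct,14.1,1,hard
icp_agreement_BC_C_pct,4.6,1,hard
pcc_BC_A,0.47,2,discordant
pcc_BC_B,0.66,2,discordant
pcc_BC_C,0.81,2,discordant
pcc_reduction_BC_A_pct,42.0,1,discordant
pcc_reduction_BC_B_pct,18.5,1,discordant
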