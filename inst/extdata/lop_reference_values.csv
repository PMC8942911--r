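quantity,reference,tolerance
g2_joint_e1,5.22,0.3
g2_joint_e2,3.974,0.3
g2_combined,9.19,0.3
dg2_Do_conditions_e1,24.31,0.5
dg2_Dncol_conditions_e1,27.77,0.5
dg2_Dncat_conditions_e2,8.75,0.5
dg2_interaction_Dncol,13.12,0.5
uvsdt_da_e1_category_colour_lure,2.716,0.03
uvsdt_xc_e1_category_colour_lure,1.640,0.03
wald_z_da_colour_lure_e1,8.38,0.02
mean_rating_e1_colour_target,3.204,0.001
fa_rate_e2_critical,0.44,0.005
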