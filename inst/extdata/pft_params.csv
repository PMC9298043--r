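pft,Vcmax_25,Jmax_to_Vcmax,f_d,quantum_yield,curvature_J,curvature_W,f_0,dq_crit,g1,a1,D0,g0,beta_cost,beta_cost_c,gsc_over_gm,LAI,g_night
BET-Tr,41,1.7,0.01,0.3,0.7,0.9,0.875,0.09,3.77,9,1.5,0,146,218.6,0.25,6,0.003
BET-Te,45,1.8,0.015,0.3,0.7,0.9,0.875,0.09,4.23,9,1.5,0,146,218.6,0.25,5,0.003
BDT,50,1.9,0.015,0.3,0.7,0.9,0.875,0.09,4.45,9,1.5,0,146,218.6,0.25,5,0.003
NET,55,1.9,0.015,0.3,0.7,0.9,0.875,0.06,2.35,9,1.5,0,146,218.6,0.25,4,0.003
NDT,50,1.9,0.015,0.3,0.7,0.9,0.875,0.06,2.35,9,1.5,0,146,218.6,0.25,4,0.003
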