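variant,parameter,value,units,source
infinite_gm,gamma_star_25,42.75,umol mol-1,"Bernacchi et al. (2001) Plant Cell Environ 24:253-259, in vivo, normalized to 25 C and 99.1 kPa"
infinite_gm,Ea_gamma_star,37830,J mol-1,"Bernacchi et al. (2001)"
infinite_gm,Kc_25,404.9,umol mol-1,"Bernacchi et al. (2001)"
infinite_gm,Ea_Kc,79430,J mol-1,"Bernacchi et al. (2001)"
infinite_gm,Ko_25,278.4,mmol mol-1,"Bernacchi et al. (2001)"
infinite_gm,Ea_Ko,36380,J mol-1,"Bernacchi et al. (2001)"
finite_gm,gamma_star_25,37.43,umol mol-1,"Bernacchi et al. (2002) Plant Physiol 130:1992-1998, chloroplast-based"
finite_gm,Ea_gamma_star,24460,J mol-1,"Bernacchi et al. (2002)"
finite_gm,Kc_25,272.38,umol mol-1,"Bernacchi et al. (2002)"
finite_gm,Ea_Kc,80990,J mol-1,"Bernacchi et al. (2002)"
finite_gm,Ko_25,165.82,mmol mol-1,"Bernacchi et al. (2002)"
finite_gm,Ea_Ko,23720,J mol-1,"Bernacchi et al. (2002)"
fractionation,a,4.4,per mil,"CO2 diffusion through stomata; Farquhar et al. (1982)"
fractionation,a_m,1.8,per mil,"dissolution + mesophyll diffusion; Farquhar et al. (1982)"
fractionation,b,30,per mil,"effective RuBisCO carboxylation; Farquhar et al. (1982)"
fractionation,b_bar,28,per mil,"lumped carboxylation absorbing the mesophyll term; Ubierna & Farquhar (2014)"
fractionation,b_prime,27,per mil,"lumped carboxylation absorbing mesophyll + photorespiration; Farquhar et al. (1982)"
fractionation,f,12,per mil,"photorespiration fractionation; Farquhar et al. (1982), uncertainty +/- 4"
physical,carbon_mass_conv,0.012,kg C mol-1 CO2,"molar mass of carbon"
physical,diffusivity_ratio,1.6,unitless,"H2O:CO2 diffusivity ratio in air"
physical,R_gas,8.314,J K-1 mol-1,"ideal gas constant"
reference,T_ref,298.15,K,"reference temperature (25 C)"
reference,P_ref,99100,Pa,"reference pressure"
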