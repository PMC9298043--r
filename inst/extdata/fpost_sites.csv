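network,site,species,years,f_post,sd
AmeriFlux,US-Ha1,QURU,"2003;2013",1.97,0.26
AmeriFlux,US-Ha1,TSCA,"2003;2013",6.08,0.25
AmeriFlux,US-Bar,FAGR,"2003;2013",4.32,0.02
AmeriFlux,US-Bar,TSCA,"2003;2013",5.71,0.68
AmeriFlux,US-DK2,CATO,"2002",3.20,NA
AmeriFlux,US-DK2,LITU,"2002",3.90,NA
AmeriFlux,US-Ho1,PIRU,"2003;2013",5.49,0.15
AmeriFlux,US-Ho1,TSCA,"2003;2013",4.08,1.88
AmeriFlux,US-SP1,PIEL,"2013",4.85,NA
AmeriFlux,US-SP1,PIPA,"2002;2013",3.64,0.47
AmeriFlux,US-MMS,ACSA,"2005",4.36,NA
AmeriFlux,US-MMS,LITU,"2005",2.74,NA
AmeriFlux,US-Slt,PIEC,"2013",4.00,NA
AmeriFlux,US-Slt,QUPR,"2013",3.00,NA
AmeriFlux,US-Fuf,PIPO,"2014",3.47,NA
CarboEuropeFlux,BE-Bra,PISY_QURO,"2001;2002",1.88,0.14
CarboEuropeFlux,IT-Col,FAGR,"2001;2002",3.00,0.72
CarboEuropeFlux,DE-Hai,FAGR,"2001;2002",1.85,0.38
CarboEuropeFlux,FI-Hyy,ABAL,"2001",2.11,NA
CarboEuropeFlux,IT-Lav,ABAL,"2002",3.44,NA
CarboEuropeFlux,FR-LBr,PIPI,"2001;2002",0.72,0.53
CarboEuropeFlux,NL-Loo,PISY,"2001;2002",2.81,0.42
CarboEuropeFlux,DK-Sor,FAGR,"2002",0.65,NA
CarboEuropeFlux,DE-Tha,PIAB,"2001;2002",3.43,0.28
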