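ester,molar_mass,fa_molar_mass,initial_mass_mg,volume_mL,cLogP,steric_hindrance,K_per_h
FA-21-Ac,494.21162,452.20105,16,100,2.79,1.24,0.0615
FA-21-EB,566.26912,452.20105,18.35,100,3.79,1.36,0.0049
FA-21-EP,552.25347,452.20105,18,100,3.26,1.34,0.0039
FA-21-MB,552.25347,452.20105,18.5,100,3.4,1.37,0.004
FA-21-MP,538.23722,452.20105,17.7,100,2.87,1.35,0.0089
FA-21-PhP,600.25347,452.20105,20,100,4.59,1.4,0.0434
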