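ester,level,q_C,q_O1,q_O2
FA-21-Ac,AM1,0.2991,-0.2830,-0.2580
FA-21-EB,AM1,0.2990,-0.2950,-0.2237
FA-21-EP,AM1,0.3062,-0.2949,-0.2284
FA-21-MB,AM1,0.2991,-0.2943,-0.2234
FA-21-MP,AM1,0.3069,-0.2940,-0.2282
FA-21-PhP,AM1,0.2777,-0.3227,-0.2851
FA-21-Ac,HF/STO-3G gas,0.3080,-0.2407,-0.2595
FA-21-EB,HF/STO-3G gas,0.2971,-0.2489,-0.2475
FA-21-EP,HF/STO-3G gas,0.3027,-0.2478,-0.2515
FA-21-MB,HF/STO-3G gas,0.2975,-0.2481,-0.2471
FA-21-MP,HF/STO-3G gas,0.3033,-0.2468,-0.2511
FA-21-PhP,HF/STO-3G gas,0.3025,-0.2575,-0.2767
FA-21-Ac,HF/6-31G gas,0.7654,-0.5207,-0.6927
FA-21-EB,HF/6-31G gas,0.7898,-0.5390,-0.6792
FA-21-EP,HF/6-31G gas,0.8195,-0.5423,-0.6837
FA-21-MB,HF/6-31G gas,0.7917,-0.5383,-0.6784
FA-21-MP,HF/6-31G gas,0.8212,-0.5413,-0.6833
FA-21-PhP,HF/6-31G gas,0.8161,-0.5598,-0.7509
FA-21-Ac,B3LYP/STO-3G gas,0.2314,-0.2095,-0.1879
FA-21-EB,B3LYP/STO-3G gas,0.2233,-0.2172,-0.1783
FA-21-EP,B3LYP/STO-3G gas,0.2277,-0.2167,-0.1807
FA-21-MB,B3LYP/STO-3G gas,0.2237,-0.2165,-0.1778
FA-21-MP,B3LYP/STO-3G gas,0.2283,-0.2157,-0.1802
FA-21-PhP,B3LYP/STO-3G gas,0.2232,-0.2207,-0.2010
FA-21-Ac,B3LYP/6-31G gas,0.5089,-0.3784,-0.4682
FA-21-EB,B3LYP/6-31G gas,0.5138,-0.3959,-0.4582
FA-21-EP,B3LYP/6-31G gas,0.5387,-0.3997,-0.4610
FA-21-MB,B3LYP/6-31G gas,0.5167,-0.5167,-0.4574
FA-21-MP,B3LYP/6-31G gas,0.5410,-0.3988,-0.4605
FA-21-PhP,B3LYP/6-31G gas,0.5518,-0.4059,-0.5214
FA-21-Ac,HF/6-31G CPCM ethanol,0.3188,-0.2719,-0.2633
FA-21-EB,HF/6-31G CPCM ethanol,0.3057,-0.2765,-0.2597
FA-21-EP,HF/6-31G CPCM ethanol,0.3086,-0.2765,-0.2616
FA-21-MB,HF/6-31G CPCM ethanol,0.3062,-0.2752,-0.2591
FA-21-MP,HF/6-31G CPCM ethanol,0.3089,-0.2748,-0.2612
FA-21-PhP,HF/6-31G CPCM ethanol,0.3107,-0.2745,-0.2736
FA-21-Ac,B3LYP/STO-3G COSMO ethanol,0.2370,-0.2395,-0.1910
FA-21-EB,B3LYP/STO-3G COSMO ethanol,0.2277,-0.2424,-0.1877
FA-21-EP,B3LYP/STO-3G COSMO ethanol,0.2287,-0.2426,-0.1883
FA-21-MB,B3LYP/STO-3G COSMO ethanol,0.2280,-0.2943,-0.1872
FA-21-MP,B3LYP/STO-3G COSMO ethanol,0.2293,-0.2940,-0.1881
FA-21-PhP,B3LYP/STO-3G COSMO ethanol,0.2281,-0.3227,-0.1979
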