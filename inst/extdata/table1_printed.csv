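level,quantity,FA-21-Ac,FA-21-EB,FA-21-EP,FA-21-MB,FA-21-MP,FA-21-PhP,R
global,d_C_O2,1.3810,1.3690,1.3700,1.3690,1.3700,1.3740,0.9627
global,d_C_O1,1.2290,1.2320,1.2320,1.2320,1.2320,1.2280,-0.9168
AM1,C,0.2991,0.2990,0.3062,0.2991,0.3069,0.2777,-0.5215
AM1,O2,-0.2580,-0.2237,-0.2284,-0.2234,-0.2282,-0.2851,-0.8342
AM1,O1,-0.2830,-0.2950,-0.2949,-0.2943,-0.2940,-0.3227,-0.0956
AM1,C-O2,0.5571,0.5226,0.5346,0.5225,0.5351,0.5628,0.9023
AM1,C-O1,0.5821,0.5940,0.6011,0.5934,0.6009,0.6004,-0.5807
AM1,P_C-O2,0.7694,0.7155,0.7324,0.7153,0.7331,0.7732,0.9247
AM1,P_C=O1,0.7154,0.7318,0.7405,0.7311,0.7403,0.7373,-0.6644
HF/STO-3G gas,C,0.3080,0.2971,0.3027,0.2975,0.3033,0.3025,0.7510
HF/STO-3G gas,O2,-0.2595,-0.2475,-0.2515,-0.2471,-0.2511,-0.2767,-0.7309
HF/STO-3G gas,O1,-0.2407,-0.2489,-0.2478,-0.2481,-0.2468,-0.2575,0.1229
HF/STO-3G gas,C-O2,0.5676,0.5446,0.5542,0.5446,0.5544,0.5792,0.8315
HF/STO-3G gas,C-O1,0.5488,0.5460,0.5505,0.5457,0.5502,0.5599,0.4620
HF/STO-3G gas,P_C-O2,0.7838,0.7455,0.7592,0.7456,0.7595,0.7958,0.8771
HF/STO-3G gas,P_C=O1,0.6745,0.6727,0.6782,0.6723,0.6778,0.6876,0.3561
HF/6-31G gas,C,0.7654,0.7898,0.8195,0.7917,0.8212,0.8161,-0.4782
HF/6-31G gas,O2,-0.6927,-0.6792,-0.6837,-0.6784,-0.6833,-0.7509,-0.5802
HF/6-31G gas,O1,-0.5207,-0.5390,-0.5423,-0.5383,-0.5413,-0.5598,0.2239
HF/6-31G gas,C-O2,1.4582,1.4689,1.5033,1.4701,1.5044,1.5670,0.1414
HF/6-31G gas,C-O1,1.2862,1.3288,1.3618,1.3300,1.3625,1.3759,-0.4076
HF/6-31G gas,P_C-O2,2.0137,2.0110,2.0595,2.0126,2.0611,2.1531,0.2631
HF/6-31G gas,P_C=O1,1.5807,1.6371,1.6778,1.6386,1.6786,1.6896,-0.4605
B3LYP/STO-3G gas,C,0.2314,0.2233,0.2277,0.2237,0.2283,0.2232,0.4277
B3LYP/STO-3G gas,O2,-0.1879,-0.1783,-0.1807,-0.1778,-0.1802,-0.2010,-0.7492
B3LYP/STO-3G gas,O1,-0.2095,-0.2172,-0.2167,-0.2165,-0.2157,-0.2207,0.4194
B3LYP/STO-3G gas,C-O2,0.4193,0.4016,0.4084,0.4015,0.4085,0.4242,0.8752
B3LYP/STO-3G gas,C-O1,0.4409,0.4405,0.4443,0.4402,0.4440,0.4439,-0.0451
B3LYP/STO-3G gas,P_C-O2,0.5790,0.5498,0.5595,0.5496,0.5596,0.5828,0.9118
B3LYP/STO-3G gas,P_C=O1,0.5418,0.5427,0.5474,0.5423,0.5470,0.5452,-0.3450
B3LYP/6-31G gas,C,0.5089,0.5138,0.5387,0.5167,0.5410,0.5518,-0.0727
B3LYP/6-31G gas,O2,-0.4682,-0.4582,-0.4610,-0.4574,-0.4605,-0.5214,-0.5609
B3LYP/6-31G gas,O1,-0.3784,-0.3959,-0.3997,-0.5167,-0.3988,-0.4059,0.4213
B3LYP/6-31G gas,C-O2,0.9771,0.9720,0.9997,0.9742,1.0016,1.0731,0.3315
B3LYP/6-31G gas,C-O1,0.8874,0.9097,0.9383,1.0334,0.9398,0.9577,-0.4469
B3LYP/6-31G gas,P_C-O2,1.3494,1.3306,1.3696,1.3336,1.3722,1.4745,0.4106
B3LYP/6-31G gas,P_C=O1,1.0906,1.1207,1.1560,1.2732,1.1578,1.1760,-0.4686
HF/6-31G CPCM ethanol,C,0.3188,0.3057,0.3086,0.3062,0.3089,0.3107,0.9101
HF/6-31G CPCM ethanol,O2,-0.2633,-0.2597,-0.2616,-0.2591,-0.2612,-0.2736,-0.6169
HF/6-31G CPCM ethanol,O1,-0.2719,-0.2765,-0.2765,-0.2752,-0.2748,-0.2745,0.8871
HF/6-31G CPCM ethanol,C-O2,0.5821,0.5655,0.5702,0.5654,0.5701,0.5843,0.9243
HF/6-31G CPCM ethanol,C-O1,0.5907,0.5822,0.5850,0.5815,0.5837,0.5852,0.8641
HF/6-31G CPCM ethanol,P_C-O2,0.8038,0.7741,0.7811,0.7740,0.7810,0.8028,0.9578
HF/6-31G CPCM ethanol,P_C=O1,0.7260,0.7173,0.7208,0.7164,0.7192,0.7186,0.7311
B3LYP/STO-3G COSMO ethanol,C,0.2370,0.2277,0.2287,0.2280,0.2293,0.2281,0.7636
B3LYP/STO-3G COSMO ethanol,O2,-0.1910,-0.1877,-0.1883,-0.1872,-0.1881,-0.1979,-0.6912
B3LYP/STO-3G COSMO ethanol,O1,-0.2395,-0.2424,-0.2426,-0.2943,-0.2940,-0.3227,-0.0345
B3LYP/STO-3G COSMO ethanol,C-O2,0.4280,0.4154,0.4171,0.4153,0.4174,0.4260,0.9853
B3LYP/STO-3G COSMO ethanol,C-O1,0.4766,0.4701,0.4713,0.5223,0.5233,0.5508,0.1160
B3LYP/STO-3G COSMO ethanol,P_C-O2,0.5911,0.5687,0.5714,0.5685,0.5719,0.5853,0.9924
B3LYP/STO-3G COSMO ethanol,P_C=O1,0.5857,0.5791,0.5807,0.6435,0.6447,0.6764,0.0966
global,steric_hindrance,1.2400,1.3600,1.3400,1.3700,1.3500,1.4000,-0.5356
global,cLogP,2.7900,3.7900,3.2600,3.4000,2.8700,4.5900,0.0533
global,K,0.0615,0.0049,0.0039,0.0040,0.0089,0.0434,1.0000
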