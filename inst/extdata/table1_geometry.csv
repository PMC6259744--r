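ester,d_C_O2,d_C_O1
FA-21-Ac,1.381,1.229
FA-21-EB,1.369,1.232
FA-21-EP,1.37,1.232
FA-21-MB,1.369,1.232
FA-21-MP,1.37,1.232
FA-21-PhP,1.374,1.228
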