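channel,STD,Mean,Max,Min,Var,Med,SKW,ENT,KRT,MOM,POW
CH2,463.10,1.61,1095.00,-1385.00,2.14E+05,17.00,-0.11,4.70,2.35,1.08E+11,1.41E+12
CH21,395.41,9.95,1279.00,-1295.00,1.56E+05,-25.00,0.26,4.47,3.00,7.33E+10,1.03E+12
CH6,388.61,4.13,941.00,-1293.00,1.51E+05,42.00,-0.40,4.84,3.01,6.86E+10,9.90E+11
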