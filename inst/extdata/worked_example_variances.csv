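channel,variance
CH1,1.44E+05
CH2,2.14E+05
CH3,9.76E+04
CH4,8.92E+04
CH5,1.37E+05
CH6,1.51E+05
CH7,4.16E+04
CH8,7.67E+04
CH9,7.23E+04
CH10,4.09E+04
CH11,2.97E+04
CH12,4.10E+04
CH13,8.32E+04
CH14,4.79E+04
CH15,8.25E+04
CH16,3.62E+04
CH17,7.22E+04
CH18,6.64E+04
CH19,9.76E+04
CH20,7.76E+04
CH21,1.56E+05
CH22,2.02E+04
CH23,8.25E+04
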