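trait,PC1,PC2,PC3,PC4,PC5,PC6,PC7,PC8,PC9,PC10
STC,0.54,0.10,-0.20,-0.44,0.39,-0.09,0.04,-0.09,0.02,0.10
GP,0.10,-0.24,-0.17,-0.41,0.42,0.25,0.07,0.24,-0.14,0.01
MPL,0.37,-0.08,0.52,0.19,0.41,0.14,0.17,0.02,-0.11,0.05
MTL,-0.07,-0.13,0.29,-0.03,0.26,0.06,-0.37,0.43,0.20,0.21
ST,0.62,-0.19,-0.24,-0.10,0.21,-0.14,0.19,-0.03,0.05,0.11
SSW,0.84,-0.25,0.07,0.12,-0.07,0.06,-0.14,-0.14,0.25,0.07
SGW,0.81,-0.25,0.08,0.15,-0.11,0.06,-0.15,-0.16,0.27,0.06
TGW,0.21,-0.23,0.39,0.49,-0.22,0.08,0.02,0.19,-0.34,-0.08
L,0.16,0.49,-0.24,0.25,0.18,0.16,0.12,0.25,0.14,-0.12
a,0.32,0.71,-0.23,0.27,-0.01,0.07,-0.09,0.02,-0.06,0.00
b,0.36,0.77,-0.26,0.32,0.07,0.11,-0.01,0.12,-0.02,-0.04
LSC,-0.34,-0.25,-0.15,0.29,0.22,0.26,0.07,-0.09,0.45,-0.08
SLC,0.21,0.43,0.36,-0.26,-0.17,-0.15,-0.07,-0.05,0.12,0.12
SZ,-0.41,-0.05,-0.22,0.39,0.13,-0.17,0.06,-0.15,0.11,0.16
SS,0.14,-0.13,-0.42,-0.15,-0.32,0.01,0.13,0.24,0.22,0.10
SE,-0.07,0.21,0.44,0.02,0.36,-0.14,0.26,0.04,-0.11,-0.16
SNC,0.08,0.02,0.04,0.02,-0.31,-0.03,0.65,0.22,0.23,0.06
SL,-0.05,0.06,0.36,-0.10,-0.03,-0.19,0.45,0.11,0.21,0.04
BC,-0.31,-0.26,-0.23,0.46,0.36,-0.01,0.05,-0.04,0.18,-0.12
AC,-0.07,-0.06,0.08,-0.08,-0.12,0.74,0.08,0.23,-0.08,0.24
HC,0.18,-0.03,0.11,-0.30,-0.10,0.29,0.01,-0.13,0.15,-0.78
SLS,-0.07,0.09,-0.11,-0.05,0.00,0.38,0.29,-0.62,-0.20,0.26
FLS,0.24,0.04,0.43,0.26,0.17,-0.02,0.04,-0.18,0.07,0.03
TL,0.39,-0.40,-0.16,0.40,-0.24,-0.06,0.06,0.09,-0.25,-0.05
LR,0.32,-0.29,-0.43,-0.01,0.19,-0.18,0.16,0.12,-0.33,-0.14
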