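trait,PC1,PC2,PC3,PC4,PC5,PC6,PC7,PC8,PC9,PC10
STC,0.298,0.064,-0.144,-0.331,0.33,-0.086,0.042,-0.084,0.023,0.105
GP,0.054,-0.158,-0.12,-0.303,0.354,0.231,0.064,0.233,-0.142,0.008
MPL,0.201,-0.053,0.364,0.14,0.348,0.132,0.157,0.018,-0.107,0.054
MTL,-0.037,-0.085,0.206,-0.022,0.22,0.051,-0.349,0.412,0.2,0.217
ST,0.343,-0.125,-0.168,-0.071,0.179,-0.132,0.178,-0.024,0.049,0.11
SSW,0.463,-0.163,0.051,0.09,-0.057,0.055,-0.129,-0.134,0.249,0.07
SGW,0.447,-0.165,0.054,0.112,-0.095,0.055,-0.14,-0.15,0.267,0.058
TGW,0.116,-0.151,0.275,0.364,-0.185,0.071,0.022,0.181,-0.34,-0.082
L,0.088,0.324,-0.169,0.188,0.15,0.151,0.112,0.241,0.138,-0.125
a,0.174,0.469,-0.164,0.198,-0.006,0.062,-0.087,0.023,-0.056,-0.003
b,0.197,0.51,-0.182,0.242,0.055,0.103,-0.012,0.114,-0.022,-0.043
LSC,-0.186,-0.167,-0.103,0.216,0.186,0.242,0.062,-0.088,0.448,-0.085
SLC,0.116,0.283,0.254,-0.196,-0.146,-0.143,-0.064,-0.049,0.115,0.125
SZ,-0.226,-0.03,-0.158,0.289,0.112,-0.162,0.056,-0.142,0.11,0.168
SS,0.077,-0.086,-0.298,-0.113,-0.268,0.007,0.121,0.234,0.214,0.106
SE,-0.04,0.142,0.312,0.014,0.301,-0.129,0.244,0.038,-0.105,-0.16
SNC,0.042,0.011,0.03,0.016,-0.261,-0.029,0.619,0.208,0.226,0.057
SL,-0.03,0.037,0.252,-0.075,-0.024,-0.173,0.424,0.109,0.209,0.045
BC,-0.169,-0.172,-0.165,0.343,0.302,-0.012,0.047,-0.038,0.182,-0.12
AC,-0.037,-0.039,0.057,-0.056,-0.098,0.687,0.071,0.223,-0.076,0.247
HC,0.097,-0.021,0.079,-0.224,-0.085,0.265,0.01,-0.124,0.145,-0.795
SLS,-0.039,0.061,-0.078,-0.034,-0.002,0.356,0.273,-0.602,-0.202,0.261
FLS,0.13,0.028,0.306,0.195,0.14,-0.015,0.039,-0.173,0.067,0.032
TL,0.217,-0.268,-0.111,0.298,-0.2,-0.051,0.057,0.09,-0.25,-0.054
LR,0.177,-0.192,-0.303,-0.005,0.158,-0.167,0.154,0.12,-0.329,-0.145
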