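locus,na,ho,he,fis,hwe_significant,fnull,pic,pi
TcUniZg004,4,0.167,0.235,0.29,FALSE,,0.219,0.605
TcUniZg005,4,0.304,0.449,0.322,FALSE,,0.384,0.37
TcUniZg006,13,0.542,0.633,0.145,FALSE,,0.605,0.158
TcUniZg007,5,0.333,0.505,0.339,FALSE,0.091,0.432,0.318
TcUniZg008,11,0.708,0.864,0.18,FALSE,,0.824,0.043
TcUniZg009,6,0.583,0.774,0.246,FALSE,0.111,0.716,0.098
TcUniZg010,6,0.667,0.757,0.12,FALSE,,0.697,0.11
TcUniZg012,5,0.391,0.542,0.277,FALSE,,0.485,0.266
TcUniZg013,4,0.375,0.323,-0.16,FALSE,,0.288,0.495
TcUniZg014,6,0.542,0.531,-0.021,FALSE,,0.488,0.263
TcUniZg017,7,0.542,0.704,0.23,FALSE,,0.639,0.146
TcUniZg019,5,0.583,0.72,0.19,FALSE,,0.654,0.137
TcUniZg020,3,0.083,0.197,0.576,FALSE,0.111,0.178,0.668
TcUniZg023,3,0.458,0.433,-0.059,FALSE,,0.35,0.405
TcUniZg032,3,0.5,0.592,0.155,FALSE,,0.506,0.25
TcUniZg037,4,0.125,0.299,0.582,TRUE,0.146,0.266,0.528
TcUniZg038,5,0.542,0.702,0.228,FALSE,,0.634,0.15
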