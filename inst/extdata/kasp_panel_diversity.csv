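marker,maf,gene_diversity,heterozygosity,pic,missing_pct
Rp0-1,0.385,0.473,0.423,0.361,0.95
Rp0-4,0.490,0.500,0.392,0.375,2.86
Rp1-2,0.352,0.456,0.419,0.352,0.00
Rp1-4,0.248,0.373,0.438,0.303,0.00
Rp1-6,0.360,0.461,0.380,0.355,4.76
Rp2-1,0.282,0.405,0.097,0.323,1.90
Rp2-2,0.252,0.377,0.390,0.306,0.00
Rp2-6,0.361,0.461,0.067,0.355,0.95
Rp3-1,0.319,0.435,0.238,0.340,0.00
Rp3-3,0.356,0.458,0.385,0.353,0.95
Rp4-1,0.199,0.319,0.340,0.268,1.90
Rp4-3,0.296,0.417,0.282,0.330,1.90
Rp4-5,0.411,0.484,0.525,0.367,3.81
Rp5-1,0.422,0.488,0.495,0.369,1.90
Rp5-3,0.252,0.377,0.406,0.306,3.81
Rp5-4,0.450,0.495,0.426,0.373,3.81
Rp6-2,0.284,0.407,0.333,0.324,2.86
Rp6-3,0.173,0.286,0.038,0.245,0.95
Rp6-4,0.271,0.396,0.086,0.317,0.00
Rp7-1,0.443,0.493,0.105,0.372,0.00
Rp7-2,0.214,0.337,0.371,0.280,0.00
Rp7-3,0.436,0.492,0.598,0.371,2.86
Rp7-5,0.421,0.487,0.584,0.369,3.81
Rp8-1,0.229,0.353,0.400,0.290,0.00
Rp8-8,0.320,0.435,0.380,0.341,4.76
Rp8-9,0.381,0.472,0.465,0.360,3.81
Rp9-1,0.311,0.428,0.427,0.337,1.90
Rp9-4,0.422,0.488,0.495,0.369,1.90
Rp9-5,0.314,0.431,0.400,0.338,0.00
Rp10-5,0.300,0.420,0.390,0.332,0.00
Rp10-8,0.228,0.352,0.277,0.290,3.81
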