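receptor,subfamily,value
BDKRB2,Gs,0.91
BDKRB2,Gi,0.88
BDKRB2,Gq,0.95
BDKRB2,G12/13,0.84
LPAR2,Gs,0.86
LPAR2,Gi,0.90
LPAR2,Gq,0.83
LPAR2,G12/13,0.12
P2RY12,Gs,0.05
P2RY12,Gi,0.93
P2RY12,Gq,0.10
P2RY12,G12/13,0.08
ADGRG2,Gs,0.15
ADGRG2,Gi,0.11
ADGRG2,Gq,0.89
ADGRG2,G12/13,0.18
CHRM1,Gs,0.24
CHRM1,Gi,0.41
CHRM1,Gq,0.97
CHRM1,G12/13,0.33
ADRB2,Gs,0.98
ADRB2,Gi,0.36
ADRB2,Gq,0.09
ADRB2,G12/13,0.06
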