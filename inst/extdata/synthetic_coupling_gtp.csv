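receptor,subfamily,value
BDKRB2,Gs,primary
BDKRB2,Gi,secondary
BDKRB2,Gq,primary
BDKRB2,G12/13,secondary
LPAR2,Gs,secondary
LPAR2,Gi,primary
LPAR2,Gq,primary
LPAR2,G12/13,none
P2RY12,Gs,none
P2RY12,Gi,primary
P2RY12,Gq,none
P2RY12,G12/13,none
CHRM1,Gs,none
CHRM1,Gi,secondary
CHRM1,Gq,primary
CHRM1,G12/13,none
ADRB2,Gs,primary
ADRB2,Gi,secondary
ADRB2,Gq,none
ADRB2,G12/13,none
HTR2A,Gs,none
HTR2A,Gi,secondary
HTR2A,Gq,primary
HTR2A,G12/13,none
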