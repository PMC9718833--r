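receptor,subfamily,value
BDKRB2,Gs,primary
BDKRB2,Gi,primary
BDKRB2,Gq,primary
BDKRB2,G12/13,primary
LPAR2,Gs,primary
LPAR2,Gi,primary
LPAR2,Gq,secondary
LPAR2,G12/13,none
P2RY12,Gs,none
P2RY12,Gi,primary
P2RY12,Gq,none
P2RY12,G12/13,secondary
ADGRG2,Gs,none
ADGRG2,Gi,none
ADGRG2,Gq,primary
ADGRG2,G12/13,none
HTR2A,Gs,none
HTR2A,Gi,none
HTR2A,Gq,primary
HTR2A,G12/13,secondary
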