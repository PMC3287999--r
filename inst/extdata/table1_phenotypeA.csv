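gene_symbol,accession,fold_change,p_value
PLIN1,NM_002666,>100,<1E-45
ITIH1,NM_002215,>100,<1E-45
PPARG,NM_138711,32.36,<1E-45
RNF150,NM_020724,12.32,1.24E-08
DLX4,NM_138281,8.65,1.45E-06
S1PR3,NM_005226,4.05,1.47E-11
FZD3,NM_017412,3.77,8.60E-04
HSD17B12,NM_016142,3.73,9.77E-35
GUSB,NM_000181,2.24,1.18E-11
MEGF6,NM_001409,-81.28,<1E-45
ITGA3,NM_002204,-13.85,1.77E-20
MYBL2,NM_002466,-9.12,7.60E-29
KRT79,NM_175834,-3.64,5.60E-04
ITGA6,NM_000210,-2.86,1.40E-04
OAZ3,NM_016178,-2.68,6.75E-16
RB1,NM_000321,-2.00,3.50E-34
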