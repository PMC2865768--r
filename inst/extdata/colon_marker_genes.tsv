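gene	regulation
DES	down
MYL9	down
CSRP1	down
ACTA2	down
SPARCL1	down
KCNMB1	down
Mgp	down
SLC2A4	down
myosin	down
TPM3	down
IL8	up
S100A11	up
HSPD1	up
HNRNPA1	up
DARS	up
SRPK1	up
IPL1	up
PCBD1	up
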