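gene	regulation	alpha	degree	indegree
DES	down	1	0	0
DES	down	0.95	2	2
DES	down	0.9	4	3
DES	down	0.85	15	10
DES	down	0.8	33	25
DES	down	average	11	8
MYL9	down	1	0	0
MYL9	down	0.95	0	0
MYL9	down	0.9	7	6
MYL9	down	0.85	22	17
MYL9	down	0.8	40	33
MYL9	down	average	14	11
CSRP1	down	1	1	1
CSRP1	down	0.95	3	2
CSRP1	down	0.9	3	2
CSRP1	down	0.85	9	5
CSRP1	down	0.8	18	13
CSRP1	down	average	7	5
ACTA2	down	1	0	0
ACTA2	down	0.95	0	0
ACTA2	down	0.9	11	10
ACTA2	down	0.85	28	22
ACTA2	down	0.8	30	22
ACTA2	down	average	14	11
SPARCL1	down	1	1	1
SPARCL1	down	0.95	2	2
SPARCL1	down	0.9	6	5
SPARCL1	down	0.85	20	13
SPARCL1	down	0.8	36	28
SPARCL1	down	average	13	10
KCNMB1	down	1	0	0
KCNMB1	down	0.95	0	0
KCNMB1	down	0.9	13	10
KCNMB1	down	0.85	24	15
KCNMB1	down	0.8	40	29
KCNMB1	down	average	15	9
Mgp	down	1	0	0
Mgp	down	0.95	0	0
Mgp	down	0.9	12	8
Mgp	down	0.85	30	21
Mgp	down	0.8	47	36
Mgp	down	average	18	13
SLC2A4	down	1	0	0
SLC2A4	down	0.95	0	0
SLC2A4	down	0.9	10	9
SLC2A4	down	0.85	27	23
SLC2A4	down	0.8	63	54
SLC2A4	down	average	20	17
myosin	down	1	0	0
myosin	down	0.95	0	0
myosin	down	0.9	0	0
myosin	down	0.85	3	1
myosin	down	0.8	10	6
myosin	down	average	3	1
TPM3	down	1	0	0
TPM3	down	0.95	0	0
TPM3	down	0.9	6	4
TPM3	down	0.85	24	18
TPM3	down	0.8	53	45
TPM3	down	average	17	13
IL8	up	1	0	0
IL8	up	0.95	0	0
IL8	up	0.9	1	1
IL8	up	0.85	2	1
IL8	up	0.8	8	4
IL8	up	average	2	1
S100A11	up	1	0	0
S100A11	up	0.95	4	3
S100A11	up	0.9	67	64
S100A11	up	0.85	1369	1367
S100A11	up	0.8	1401	1399
S100A11	up	average	568	567
HSPD1	up	1	0	0
HSPD1	up	0.95	0	0
HSPD1	up	0.9	0	0
HSPD1	up	0.85	8	7
HSPD1	up	0.8	28	27
HSPD1	up	average	7	7
HNRNPA1	up	1	0	0
HNRNPA1	up	0.95	0	0
HNRNPA1	up	0.9	6	6
HNRNPA1	up	0.85	57	55
HNRNPA1	up	0.8	1752	1747
HNRNPA1	up	average	363	362
DARS	up	1	0	0
DARS	up	0.95	0	0
DARS	up	0.9	0	0
DARS	up	0.85	7	5
DARS	up	0.8	37	33
DARS	up	average	9	8
SRPK1	up	1	0	0
SRPK1	up	0.95	0	0
SRPK1	up	0.9	2	2
SRPK1	up	0.85	9	9
SRPK1	up	0.8	22	21
SRPK1	up	average	7	6
IPL1	up	1	0	0
IPL1	up	0.95	6	6
IPL1	up	0.9	57	57
IPL1	up	0.85	1772	1770
IPL1	up	0.8	1787	1785
IPL1	up	average	724	724
PCBD1	up	1	0	0
PCBD1	up	0.95	13	13
PCBD1	up	0.9	84	83
PCBD1	up	0.85	1569	1568
PCBD1	up	0.8	1595	1591
PCBD1	up	average	652	651
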