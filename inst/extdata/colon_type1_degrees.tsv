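gene	regulation	alpha	degree	indegree
DES	down	1	0	0
DES	down	0.95	1	1
DES	down	0.9	2	2
DES	down	0.85	10	5
DES	down	0.8	14	6
DES	down	0.75	17	8
DES	down	0.7	22	13
DES	down	average	9	5
MYL9	down	1	0	0
MYL9	down	0.95	0	0
MYL9	down	0.9	2	1
MYL9	down	0.85	9	3
MYL9	down	0.8	12	4
MYL9	down	0.75	24	13
MYL9	down	0.7	27	15
MYL9	down	average	12	5
CSRP1	down	1	0	0
CSRP1	down	0.95	1	0
CSRP1	down	0.9	2	0
CSRP1	down	0.85	10	4
CSRP1	down	0.8	20	12
CSRP1	down	0.75	23	13
CSRP1	down	0.7	27	16
CSRP1	down	average	12	6
ACTA2	down	1	0	0
ACTA2	down	0.95	0	0
ACTA2	down	0.9	4	3
ACTA2	down	0.85	9	3
ACTA2	down	0.8	12	3
ACTA2	down	0.75	18	5
ACTA2	down	0.7	27	13
ACTA2	down	average	10	4
SPARCL1	down	1	0	0
SPARCL1	down	0.95	1	1
SPARCL1	down	0.9	4	3
SPARCL1	down	0.85	10	3
SPARCL1	down	0.8	15	7
SPARCL1	down	0.75	20	8
SPARCL1	down	0.7	27	15
SPARCL1	down	average	11	5
KCNMB1	down	1	0	0
KCNMB1	down	0.95	0	0
KCNMB1	down	0.9	6	3
KCNMB1	down	0.85	13	4
KCNMB1	down	0.8	14	4
KCNMB1	down	0.75	29	15
KCNMB1	down	0.7	29	15
KCNMB1	down	average	13	6
Mgp	down	1	0	0
Mgp	down	0.95	0	0
Mgp	down	0.9	4	0
Mgp	down	0.85	11	2
Mgp	down	0.8	16	4
Mgp	down	0.75	26	13
Mgp	down	0.7	27	13
Mgp	down	average	12	5
SLC2A4	down	1	0	0
SLC2A4	down	0.95	0	0
SLC2A4	down	0.9	1	0
SLC2A4	down	0.85	5	1
SLC2A4	down	0.8	12	2
SLC2A4	down	0.75	24	11
SLC2A4	down	0.7	25	11
SLC2A4	down	average	10	4
myosin	down	1	0	0
myosin	down	0.95	0	0
myosin	down	0.9	0	0
myosin	down	0.85	3	0
myosin	down	0.8	7	3
myosin	down	0.75	15	10
myosin	down	0.7	19	14
myosin	down	average	6	4
TPM3	down	1	0	0
TPM3	down	0.95	1	0
TPM3	down	0.9	4	2
TPM3	down	0.85	13	6
TPM3	down	0.8	18	9
TPM3	down	0.75	22	9
TPM3	down	0.7	22	9
TPM3	down	average	11	5
IL8	up	1	0	0
IL8	up	0.95	0	0
IL8	up	0.9	1	1
IL8	up	0.85	3	1
IL8	up	0.8	6	2
IL8	up	0.75	21	9
IL8	up	0.7	22	9
IL8	up	average	8	3
S100A11	up	1	0	0
S100A11	up	0.95	1	0
S100A11	up	0.9	2	0
S100A11	up	0.85	14	12
S100A11	up	0.8	16	13
S100A11	up	0.75	21	13
S100A11	up	0.7	26	15
S100A11	up	average	11	8
HSPD1	up	1	0	0
HSPD1	up	0.95	0	0
HSPD1	up	0.9	0	0
HSPD1	up	0.85	3	2
HSPD1	up	0.8	7	5
HSPD1	up	0.75	14	6
HSPD1	up	0.7	15	6
HSPD1	up	average	6	3
HNRNPA1	up	1	0	0
HNRNPA1	up	0.95	0	0
HNRNPA1	up	0.9	2	2
HNRNPA1	up	0.85	5	3
HNRNPA1	up	0.8	17	12
HNRNPA1	up	0.75	22	13
HNRNPA1	up	0.7	27	13
HNRNPA1	up	average	10	6
DARS	up	1	0	0
DARS	up	0.95	0	0
DARS	up	0.9	0	0
DARS	up	0.85	3	1
DARS	up	0.8	7	3
DARS	up	0.75	13	5
DARS	up	0.7	18	5
DARS	up	average	6	2
SRPK1	up	1	0	0
SRPK1	up	0.95	0	0
SRPK1	up	0.9	0	0
SRPK1	up	0.85	1	1
SRPK1	up	0.8	5	3
SRPK1	up	0.75	10	4
SRPK1	up	0.7	15	5
SRPK1	up	average	4	2
IPL1	up	1	0	0
IPL1	up	0.95	0	0
IPL1	up	0.9	0	0
IPL1	up	0.85	13	11
IPL1	up	0.8	14	11
IPL1	up	0.75	20	12
IPL1	up	0.7	25	13
IPL1	up	average	10	7
PCBD1	up	1	0	0
PCBD1	up	0.95	1	1
PCBD1	up	0.9	2	1
PCBD1	up	0.85	14	13
PCBD1	up	0.8	17	12
PCBD1	up	0.75	21	12
PCBD1	up	0.7	26	13
PCBD1	up	average	12	7
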