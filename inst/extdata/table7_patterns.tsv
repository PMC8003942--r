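gene_label	NT	LE1h	LE2h	LE4h	model
AKT1(1)	4	1	1	1	13
AKT1(2)	1	1	1	1	4
AKT1(3)	2	3	3	3	8
MET(1)	1	3	3	3	1
MET(2)	1	4	4	4	3
MET(3)	4	4	4	4	14
MET(4)	1	3	4	4	2
KRAS(1)	1	3	3	3	1
KRAS(2)	4	1	1	2	NA
KRAS(3)	1	2	2	2	5
KRAS(4)	4	4	4	4	14
NRAS(1)	4	1	1	1	13
NRAS(2)	1	3	3	3	1
EGFR(1)	1	3	3	3	1
EGFR(2)	4	4	4	4	14
EGFR(3)	4	1	1	1	13
EGFR(4)	1	2	2	2	5
EGFR(5)	2	3	3	3	8
EGFR(6)	3	2	2	2	12
EGFR(7)	1	1	1	1	4
EGFR(8)	2	1	1	1	10
BRAF	1	2	2	2	5
ALK(1)	2	4	4	4	9
ALK(2)	2	4	4	2	7
PIK3CA(1)	1	3	3	3	1
PIK3CA(2)	1	1	1	1	4
SMEK1	4	2	2	2	15
RET(1)	2	2	2	2	6
RET(2)	2	3	3	3	8
RET(3)	2	3	3	3	8
ROS1	2	3	3	1	11
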