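gene	cadd10_parents	cadd10_probands	missense_splice_parents	missense_splice_probands	union_parents	union_probands
ABCC6	1	0	2	0	2	0
AF001548.6	1	0	0	0	1	0
AKAP9	0	0	0	1	0	1
CAMK2B	0	1	0	0	0	1
CDK11A	0	1	0	1	0	1
CTD-2245F17.6	0	2	0	0	0	2
FANCA	0	1	0	1	0	2
FKBP15	1	0	1	0	1	0
MYH11	1	0	1	0	1	0
NDE1	0	2	0	0	0	2
OR2L1P	0	1	0	0	0	1
OR2L2	0	1	2	0	2	0
PITRM1-AS1	0	0	0	0	0	1
PPL	1	0	1	0	1	0
PRAMEF4	0	0	0	1	0	1
RP11-15A1.2	0	2	0	0	0	2
ZNF257	0	1	0	1	0	1
ZNF45	0	0	0	2	0	2
ZNF92	0	0	0	4	0	4
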