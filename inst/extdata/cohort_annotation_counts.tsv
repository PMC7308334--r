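category	probands	parents
utr3	3	1
downstream_gene	4	3
intron	36	19
missense	8	7
missense_splice_region	1	0
noncoding_exon	2	2
splice_region_intron	2	0
synonymous	7	7
upstream_gene	5	2
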