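cell_line	gene	protein_change	alt_reads	ref_reads
KASUMI-1	TP53	p.R248Q	52	0
COLO-818	TP53	p.C135R	34	0
IGR-37	TP53	p.C229fs	110	11
HCC202	TP53	p.T284fs	35	4
EFM-192A	TP53	p.F270fs	7	1
NCI-H1568	TP53	p.H179R	89	1
COLO-783	TP53	p.P27L	38	0
GA-10	TP53	p.I232N	94	50
GA-10	TP53	p.P152L	52	76
VMRC-RCW	TP53	p.I332_splice	192	68
JHH-5	TP53	p.PPQH190del	107	41
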