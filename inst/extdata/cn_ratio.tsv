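cell_line	cn_ratio
KASUMI-1	0.54
COLO-818	1.14
IGR-37	0.59
HCC202	0.8
EFM-192A	0.74
NCI-H1568	0.82
COLO-783	1.05
GA-10	0.81
VMRC-RCW	1.65
JHH-5	1.03
HDLM-2	0.94
RERF-LC-KJ	1.3
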