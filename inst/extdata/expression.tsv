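probe	KASUMI-1	COLO-818	IGR-37	HCC202	EFM-192A	NCI-H1568	COLO-783	GA-10	VMRC-RCW	JHH-5	HDLM-2	RERF-LC-KJ
201746_at	265	257	9	14	10	202	304	493	63	272	1	25
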