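cell_line	compound	prediction	observed
KASUMI-1	NVP-CGM097	insensitive	insensitive
COLO-818	NVP-CGM097	insensitive	insensitive
IGR-37	NVP-CGM097	insensitive	insensitive
HCC202	NVP-CGM097	insensitive	insensitive
EFM-192A	NVP-CGM097	insensitive	insensitive
NCI-H1568	NVP-CGM097	insensitive	insensitive
COLO-783	NVP-CGM097	sensitive	insensitive
GA-10	NVP-CGM097	insensitive	insensitive
VMRC-RCW	NVP-CGM097	insensitive	insensitive
JHH-5	NVP-CGM097	insensitive	insensitive
HDLM-2	NVP-CGM097	insensitive	insensitive
RERF-LC-KJ	NVP-CGM097	insensitive	insensitive
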