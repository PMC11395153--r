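cell_line,allele,source
JURKAT,HLA-A * 03:01,TCLP
JURKAT,HLA-A * 03:01,TCLP
JURKAT,HLA-B * 07:02,TCLP
JURKAT,HLA-B * 35:03,TCLP
JURKAT,HLA-C * 04:01,TCLP
JURKAT,HLA-C * 07:02,TCLP
JURKAT,HLA-DQB1 * 06:11′,TCLP
JURKAT,HLA-DQB1 * 06:11,TCLP
JURKAT,HLA-DRB1 * 15:01,TCLP
JURKAT,HLA-DRB1 * 14:18′,TCLP
H460,HLA-A * 68:01′,TCLP
H460,HLA-A * 24:02,TCLP
H460,HLA-B * 51:01′,TCLP
H460,HLA-B * 35:01,TCLP
H460,HLA-C * 15:02,TCLP
H460,HLA-C * 03:03,TCLP
H460,HLA-DQB1 * 05:01,TCLP
H460,HLA-DQB1 * 05:01,TCLP
H460,HLA-DRB1 * 01:01,TCLP
H460,HLA-DRB1 * 01:01,TCLP
Caco-2,HLA-A * 02:01,TCLP
Caco-2,HLA-A * 02:01,TCLP
Caco-2,HLA-B * 15:01′,TCLP
Caco-2,HLA-B * 15:01,TCLP
Caco-2,HLA-C * 04:01,TCLP
Caco-2,HLA-C * 04:01,TCLP
Caco-2,HLA-DRB1 * 04:05′,TCLP
Caco-2,HLA-DRB1 * 04:05,TCLP
MDA-MB-231,HLA-A * 02:17′,TCLP
MDA-MB-231,HLA-A * 02:17,TCLP
MDA-MB-231,HLA-B * 41:01,TCLP
MDA-MB-231,HLA-B * 40:02′,TCLP
MDA-MB-231,HLA-C * 02:02,TCLP
MDA-MB-231,HLA-C * 17:01,TCLP
MDA-MB-231,HLA-DQA1 * 01:02′,TCLP
MDA-MB-231,HLA-DQA1 * 01:02,TCLP
MDA-MB-231,HLA-DQB1 * 02:02′,TCLP
MDA-MB-231,HLA-DQB1 * 03:04′,TCLP
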