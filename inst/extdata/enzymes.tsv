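name	recognition	top_cut_offset	blocking_cpg_offset	methylation_sensitive
SbfI	CCTGCAGG	6	NA	FALSE
HpaII	CCGG	1	1	TRUE
MspI	CCGG	1	NA	FALSE
StuI	AGGCCT	3	NA	FALSE
NcoI	CCATGG	1	NA	FALSE
AseI	ATTAAT	2	NA	FALSE
BspHI	TCATGA	1	NA	FALSE
PacI	TTAATTAA	5	NA	FALSE
SwaI	ATTTAAAT	4	NA	FALSE
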