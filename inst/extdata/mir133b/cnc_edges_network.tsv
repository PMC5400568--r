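# Co-expression edges of the worked-example ceRNA network: the nine
# lncRNA-mRNA pairings of the published network (UBD and EPAS1 with two
# lncRNAs each, CES1 with five). Correlation values are synthetic
# stand-ins above the |PCC| >= 0.995, FDR < 0.05 screen; signs follow the
# lncRNA's DE direction (positive for tumor-up lncRNAs). The decoy edge
# ENST00000999999-UBD passes the correlation screen but must be removed
# by the dual-predictor MRE consensus during assembly.
lncRNA_id	mRNA_id	r	p	q	sign
ENST00000520055	UBD	0.9981	1.2e-16	4.1e-15	positive
ENST00000535511	UBD	0.9978	2.0e-16	4.1e-15	positive
ENST00000563610	EPAS1	-0.9962	8.3e-15	5.5e-14	negative
ENST00000573075	EPAS1	0.9955	1.4e-14	7.0e-14	positive
ENST00000366185	CES1	-0.9969	4.4e-15	4.4e-14	negative
ENST00000433005	CES1	-0.9984	9.0e-17	4.1e-15	negative
ENST00000521025	CES1	-0.9953	1.7e-14	7.7e-14	negative
ENST00000558237	CES1	-0.9975	4.0e-16	4.5e-15	negative
ENST00000571975	CES1	-0.9958	1.1e-14	6.2e-14	negative
ENST00000999999	UBD	0.9966	5.6e-15	4.7e-14	positive
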