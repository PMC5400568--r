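# Tumor-vs-normal differential-expression records for the worked example
# (mRNA side). Values are synthetic stand-ins encoding the criteria:
# candidates are up-regulated with fc >= 2 and p < 0.05; SELP passes here
# but fails the response criterion; CTGF fails the response fc threshold;
# GULP2 is up in tumor but absent from the response table.
probe_id	gene_symbol	fc	direction	p
PR_RHOA	RHOA	2.5	up	0.020
PR_TMEM71	TMEM71	2.9	up	0.011
PR_LTBP1	LTBP1	2.2	up	0.034
PR_EPAS1	EPAS1	3.6	up	0.003
PR_UBD	UBD	5.1	up	0.0005
PR_NR3C1	NR3C1	2.1	up	0.044
PR_CES1	CES1	2.7	up	0.009
PR_GULP1	GULP1	2.3	up	0.027
PR_CTGF	CTGF	2.8	up	0.015
PR_TBPL1	TBPL1	2.4	up	0.022
PR_SELP	SELP	3.0	up	0.007
PR_GULP2	GULP2	2.6	up	0.018
PR_DECOYNOMRE	DECOYNOMRE	2.9	up	0.013
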