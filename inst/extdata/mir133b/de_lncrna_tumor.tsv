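# lncRNAs passing the tumor-vs-normal DE filter in the worked example.
# Of the nine network lncRNAs, three are up- and six down-regulated;
# ENST00000520055 and ENST00000535511 directions follow the qPCR-validated
# up-regulation, the remaining assignments are illustrative. Statistics
# are synthetic stand-ins that pass fc >= 2, p < 0.05.
# ENST00000999999 (decoy, no dual-predictor MRE) also passes DE here.
probe_id	fc	direction	p
ENST00000520055	3.2	up	0.004
ENST00000535511	4.1	up	0.001
ENST00000573075	2.3	up	0.030
ENST00000563610	2.8	down	0.012
ENST00000366185	2.5	down	0.021
ENST00000433005	3.7	down	0.002
ENST00000521025	2.2	down	0.041
ENST00000558237	2.9	down	0.008
ENST00000571975	2.4	down	0.026
ENST00000999999	3.5	down	0.003
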