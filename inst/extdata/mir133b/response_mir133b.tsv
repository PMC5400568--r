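# miR-133b overexpression response table for the worked CRC example.
# Gene membership follows the published candidate screen; fold changes and
# p-values are synthetic stand-ins chosen only to encode pass/fail of the
# inclusion criteria (down on overexpression, fc >= 2, p < 0.05).
# CTGF / TBPL1 / SELP / DECOYNOMRE are deliberate non-candidates.
gene_symbol	fc	direction	p
RHOA	3.1	down	0.004
TMEM71	2.6	down	0.012
LTBP1	2.9	down	0.008
EPAS1	3.4	down	0.002
UBD	4.2	down	0.001
NR3C1	2.4	down	0.019
CES1	2.8	down	0.006
GULP1	2.2	down	0.031
CTGF	1.6	down	0.003
TBPL1	2.7	up	0.010
SELP	2.5	down	0.220
DECOYNOMRE	3.0	down	0.005
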