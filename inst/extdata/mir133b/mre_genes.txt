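# Gene symbols with miR-133b MRE support for the worked example
# (mRNA side of the combined analysis). DECOYNOMRE is intentionally
# absent; CTGF/TBPL1/SELP carry MREs but fail other criteria.
RHOA
TMEM71
LTBP1
EPAS1
UBD
NR3C1
CES1
GULP1
CTGF
TBPL1
SELP
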