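# miR-133b MRE prediction support records for the nine lncRNAs of the
# worked CRC example, each supported by both the PITA and RNA22
# predictors. ENST00000366185 is used throughout for the CES1-linked
# lncRNA that one published table prints as ENST00000361155 (an apparent
# typographical inconsistency between the printed tables; the counts are
# unchanged either way). ENST00000999999 is a decoy supported by RNA22
# only, so the dual-predictor consensus must exclude it.
transcript_id	mirna_name	predictor
ENST00000520055	miR-133b	PITA
ENST00000520055	miR-133b	RNA22
ENST00000535511	miR-133b	PITA
ENST00000535511	miR-133b	RNA22
ENST00000563610	miR-133b	PITA
ENST00000563610	miR-133b	RNA22
ENST00000573075	miR-133b	PITA
ENST00000573075	miR-133b	RNA22
ENST00000366185	miR-133b	PITA
ENST00000366185	miR-133b	RNA22
ENST00000433005	miR-133b	PITA
ENST00000433005	miR-133b	RNA22
ENST00000521025	miR-133b	PITA
ENST00000521025	miR-133b	RNA22
ENST00000558237	miR-133b	PITA
ENST00000558237	miR-133b	RNA22
ENST00000571975	miR-133b	PITA
ENST00000571975	miR-133b	RNA22
ENST00000999999	miR-133b	RNA22
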