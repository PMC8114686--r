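phase	marker	compartment
RORG	RORG	Nucleoplasm
SIRT1	SIRT1	Nucleoplasm
ARNTL-CLOCK	ARNTL(Ac@L538|P@S90):CLOCK(ADPr):CSNK2A	Nucleoplasm
PER-CRY	PER1:CRY1:CRY2:ARNTL(Ac@L538|P@S90):CLOCK(ADPr):PER2(Ac):CSNK1D:CSNK1E	Nucleoplasm
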