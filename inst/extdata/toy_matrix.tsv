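sample	NEK2	TPX2	CKS1B	UBE2C	CDKN3
TCGA-2H-A9GF-01	1	1	0	1	1
TCGA-2H-A9GG-01	0	0	0	0	0
TCGA-2H-A9GH-01	1	1	1	1	1
TCGA-2H-A9GI-01	1	0	1	1	1
TCGA-2H-A9GJ-01	0	1	0	0	0
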