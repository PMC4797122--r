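# id	smiles
SMI1	OC(O)=O
SMI2	CCCCC(O)=C4
ASA	CC(=O)Oc1ccccc1C(=O)O
CAF	Cn1cnc2c1c(=O)n(C)c(=O)n2C
ETH	CCO
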