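dataset	assembler	ms
hsa	Trinity	12.38
hsa	Oases	6.31
hsa	Trans-ABySS	14.24
hsa	SOAPdenovo-Trans	11.92
hsa	Bridger	11.13
hsa	BinPacker	6.59
hsa	IDBA-Tran	8.61
hsa	Shannon	10.3
hsa	SPAdes-sc	11.47
hsa	SPAdes-rna	12.03
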