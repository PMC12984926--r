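source	target	edge_type	evidence	site
POSP001	KINA	binary_interactor	synthetic_ppi_db	S101
POSP001	KINA	substrate_of	synthetic_kinase_pred	
NEGP001	KINA	kinase_of	synthetic_kinase_pred	
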