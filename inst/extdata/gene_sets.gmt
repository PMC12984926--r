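metabolic_signaling	synthetic set	POSP001	NULL001	NULL002	NULL003
cytoskeleton	synthetic set	NEGP001	NULL004	NULL005
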