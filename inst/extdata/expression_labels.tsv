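protein	direction	context	activity_sites
POSP001	up	synthetic_disease_cohort	S101
NEGP001	up	synthetic_disease_cohort	
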