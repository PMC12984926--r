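site_id	protein	residue	position	role
KINA:S100	KINA	S	100	anchor
POSP001:S101	POSP001	S	101	positive_partner
NEGP001:S101	NEGP001	S	101	negative_partner
NULL001:S101	NULL001	S	101	null
NULL002:S102	NULL002	S	102	null
NULL003:S103	NULL003	S	103	null
NULL004:S104	NULL004	S	104	null
NULL005:S105	NULL005	S	105	null
NULL006:S106	NULL006	S	106	null
NULL007:S107	NULL007	S	107	null
NULL008:S108	NULL008	S	108	null
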