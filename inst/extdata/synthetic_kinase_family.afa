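>KINA
CFPTPKCMSQCNVAMDKQTSYYMYYLEHYSYDCTTDAGYKRPSMSTWNFSGDAMWKDMYQSEQTIKYSVMCWNTCKSPGETRSPHDEHMQMKRCILWCTSCMACDPFFCTESKVCPLAWA
>KINB
AKPTPNARKQCEVFDDVQTIIYVYALELHANDVAFGAGAPHPSYATWMCSGDIMWKDRYTSEQTWKCHVAWWNRCWEVGEDRSPHEEHWQPKRCIAWCTTCMAVDPFGCRERKVRGLAWE
>KINC
VRATPTCMMQNNVWMDKQPSYPMYNLEHIDYDMTTYAGSKRPSPGKHNFSGLAMIEWMYASEQVIKNSVDCWLTCKFVYETLSPWDEMFTMKTDILWCTSCMACDPMFYVESKEPDPAWA
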