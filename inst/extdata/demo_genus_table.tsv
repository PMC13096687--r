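genus	family	slp	species_richness	regions
Psychotria	Rubiaceae	1	1600	BZN|COL|PER|VEN
Palicourea	Rubiaceae	1	800	BZN|COL|ECU
Coffea	Rubiaceae	0	130	ETH|TAN|MDG
Primula	Primulaceae	1	500	CHN|NEP|AUT
Linum	Linaceae	1	200	SPA|MOR|TUR
Quercus	Fagaceae	0	430	SPA|CHN|MXC
Erica	Ericaceae	0	850	CPP|SPA|MOR
Carex	Cyperaceae	0	2000	AUT|CHN|MXC
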