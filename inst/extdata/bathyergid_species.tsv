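species_code	species_name	genus	sociality	ecogroup
BJ	Bathyergus janetta	Bathyergus	Solitary	Subterranean
BS	Bathyergus suillus	Bathyergus	Solitary	Subterranean
CHH	Cryptomys hottentotus hottentotus	Cryptomys	Social	Subterranean
CHN	Cryptomys hottentotus natalensis	Cryptomys	Social	Subterranean
CHP	Cryptomys hottentotus pretoriae	Cryptomys	Social	Subterranean
CM	Fukomys mechowi	Fukomys	Social	Subterranean
CA	Fukomys amatus	Fukomys	Social	Subterranean
CAN	Fukomys anselli	Fukomys	Social	Subterranean
CB	Fukomys bocagei	Fukomys	Social	Subterranean
CDM	Fukomys damarensis	Fukomys	Social	Subterranean
CD	Fukomys darlingi	Fukomys	Social	Subterranean
GC	Georychus capensis	Georychus	Solitary	Subterranean
HA	Heliophobius argentocinereus	Heliophobius	Solitary	Subterranean
HG	Heterocephalus glaber	Heterocephalus	Social	Subterranean
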