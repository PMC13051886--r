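tf	target	weight
FOXP3	FOXP3	1
FOXP3	IKZF2	1
FOXP3	PRDM1	1
FOXP3	CTLA4	1
FOXP3	PDCD1	1
FOXP3	LAG3	1
FOXP3	IL10	1
FOXP3	TGFB1	1
FOXP3	IL2RA	1
FOXP3	ENTPD1	1
FOXP3	NT5E	1
FOXP3	IKZF4	1
FOXP3	GZMB	1
FOXP3	ENPP1	1
RORC	RORC	1
RORC	BATF	1
RORC	STAT3	1
RORC	IL17A	1
RORC	IL17F	1
RORC	IL22	1
RORC	IL23R	1
RORC	KLRB1	1
STAT3	RORC	1
STAT3	BATF	1
STAT3	STAT3	1
STAT3	IL17A	1
STAT3	IL17F	1
STAT3	G00001	-1
STAT3	G00002	-1
STAT3	G00003	-1
STAT3	G00004	-1
STAT3	G00005	-1
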