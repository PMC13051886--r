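Treg	CD8 Treg program markers	FOXP3	IKZF2	PRDM1	CTLA4	PDCD1	LAG3	IL10	TGFB1	IL2RA	ENTPD1	NT5E	IKZF4	GZMB	ENPP1
Tc17	Tc17 program markers	RORC	BATF	STAT3	IL17A	IL17F	IL22	IL23R	KLRB1
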