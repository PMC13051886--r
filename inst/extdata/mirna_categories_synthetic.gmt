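th17_cell_differentiation	synthetic miRNA category fixture	miR-0001	miR-0002	miR-0003	miR-0004	miR-0005	miR-0006	miR-0007	miR-0008	miR-0009	miR-0010	miR-0011	miR-0012
t_cell_differentiation	synthetic miRNA category fixture	miR-0003	miR-0005	miR-0013	miR-0014	miR-0015	miR-0016	miR-0017	miR-0018	miR-0019	miR-0020
apoptosis_regulation	synthetic miRNA category fixture	miR-0021	miR-0022	miR-0023	miR-0024	miR-0025	miR-0026	miR-0027	miR-0028	miR-0029	miR-0030	miR-0031	miR-0032
cell_migration	synthetic miRNA category fixture	miR-0008	miR-0033	miR-0034	miR-0035	miR-0036	miR-0037	miR-0038	miR-0039	miR-0040	miR-0041
cholesterol_efflux	synthetic miRNA category fixture	miR-0042	miR-0043	miR-0044	miR-0045	miR-0046	miR-0047	miR-0048	miR-0049	miR-0050
inflammatory_response	synthetic miRNA category fixture	miR-0002	miR-0009	miR-0051	miR-0052	miR-0053	miR-0054	miR-0055	miR-0056	miR-0057	miR-0058
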