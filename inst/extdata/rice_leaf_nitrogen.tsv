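metabolite	n_atoms
chl_GLU	1
chl_ATP	5
chl_NADPH	7
chl_ALA	1
chl_ADP	5
chl_Pi	0
chl_NADP	7
chl_PBG	2
chl_H2O	0
chl_HMB	4
chl_NH3	1
chl_UROGEN	4
chl_CPPGEN	4
chl_CO2	0
chl_O2	0
chl_PPGEN	4
chl_PPIX	4
chl_MGPP	4
chl_SAM	6
chl_MGPPME	4
chl_AdoHcy	6
chl_DVPCHLDE	4
chl_PCHLDE	4
chl_CHLDE	4
chl_GAP	0
chl_PYR	0
chl_GGPP	0
chl_PHYPP	0
chl_CHLA	4
chl_PPI	0
x_Chla	4
chl_GLN	2
cyt_GLU	1
cyt_NH3	1
cyt_ATP	5
cyt_GLN	2
cyt_ADP	5
cyt_Pi	0
chl_2OG	0
cyt_SER	1
cyt_THF	7
cyt_GLY	1
cyt_METHF	7
cyt_H2O	0
cyt_NADH	7
cyt_5MTHF	7
cyt_NAD	7
cyt_HCY	1
cyt_MET	1
cyt_SAM	6
cyt_PPI	0
cyt_AdoHcy	6
cyt_ADN	5
cyt_AMP	5
cyt_PGA	0
cyt_3PHP	0
cyt_3PSER	1
cyt_2OG	0
mit_GLY	1
mit_THF	7
mit_NAD	7
mit_METHF	7
mit_NH3	1
mit_CO2	0
mit_NADH	7
mit_H2O	0
mit_SER	1
mit_CIT	0
mit_ACON	0
mit_ICIT	0
mit_2OG	0
cyt_PYR	0
cyt_COA	7
cyt_ACCOA	7
cyt_CO2	0
cyt_OAA	0
cyt_CIT	0
cyt_MAL	0
chl_RUBP	0
chl_PGA	0
chl_PGLY	0
chl_DPGA	0
chl_DHAP	0
chl_FBP	0
chl_F6P	0
chl_X5P	0
chl_E4P	0
chl_SBP	0
chl_S7P	0
chl_R5P	0
chl_RU5P	0
chl_PEP	0
chl_OAA	0
chl_MAL	0
chl_GLYC	0
per_GLYC	0
per_O2	0
per_GLX	0
per_H2O2	0
per_H2O	0
per_SER	1
per_NADH	7
per_GLY	1
per_GLYCERATE	0
per_NAD	7
per_MAL	0
per_OAA	0
chl_GLYCERATE	0
x_Photon	0
chl_PHOT	0
cyt_O2	0
x_Ammonia	1
x_CO2	0
x_O2	0
x_H2O	0
x_Pi	0
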