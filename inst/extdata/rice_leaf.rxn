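# chlorofba reaction file
# id	equation	lb	ub	subsystem	gpr
chl_GluToALA	chl_GLU + chl_ATP + chl_NADPH -> chl_ALA + chl_ADP + chl_Pi + chl_NADP	0	1000	chlorophyll	OsHEMA AND OsGSA
chl_ALAD	2 chl_ALA -> chl_PBG + 2 chl_H2O	0	1000	chlorophyll	OsHEMB
chl_HMBS	4 chl_PBG -> chl_HMB + 4 chl_NH3	0	1000	chlorophyll	OsHEMC
chl_UROS	chl_HMB -> chl_UROGEN + chl_H2O	0	1000	chlorophyll	OsHEMD
chl_UROD	chl_UROGEN -> chl_CPPGEN + 4 chl_CO2	0	1000	chlorophyll	OsHEME
chl_CPO	chl_CPPGEN + chl_O2 -> chl_PPGEN + 2 chl_CO2 + 2 chl_H2O	0	1000	chlorophyll	OsHEMF
chl_PPO	chl_PPGEN + 1.5 chl_O2 -> chl_PPIX + 3 chl_H2O	0	1000	chlorophyll	OsHEMG
chl_MgChel	chl_PPIX + chl_ATP -> chl_MGPP + chl_ADP + chl_Pi	0	1000	chlorophyll	OsCHLH AND OsCHLI AND OsCHLD
chl_CHLM	chl_MGPP + chl_SAM -> chl_MGPPME + chl_AdoHcy	0	1000	chlorophyll	OsCHLM
chl_MgCyclase	chl_MGPPME + chl_NADPH + chl_O2 -> chl_DVPCHLDE + chl_NADP + 2 chl_H2O	0	1000	chlorophyll	OsCRD1
chl_DVR	chl_DVPCHLDE + chl_NADPH -> chl_PCHLDE + chl_NADP	0	1000	chlorophyll	OsDVR
chl_POR	chl_PCHLDE + chl_NADPH -> chl_CHLDE + chl_NADP	0	1000	chlorophyll	OsPORA OR OsPORB
chl_MEP_GGPP	4 chl_GAP + 4 chl_PYR + 2 chl_ATP + 4 chl_NADPH -> chl_GGPP + 4 chl_CO2 + 2 chl_ADP + 4 chl_Pi + 4 chl_NADP	0	1000	isoprenoid	OsDXS AND OsDXR
chl_GGR	chl_GGPP + 3 chl_NADPH -> chl_PHYPP + 3 chl_NADP	0	1000	isoprenoid	OsCHLP
chl_CHLsyn	chl_CHLDE + chl_PHYPP -> chl_CHLA + chl_PPI	0	1000	chlorophyll	OsCHLG
chl_PPase	chl_PPI + chl_H2O -> 2 chl_Pi	0	1000	chlorophyll	
chlorophyll_tx	chl_CHLA -> x_Chla	0	1000	demand	
chl_GS2	chl_GLU + chl_NH3 + chl_ATP -> chl_GLN + chl_ADP + chl_Pi	0	1000	nitrogen	OsGLN2
cyt_GS1	cyt_GLU + cyt_NH3 + cyt_ATP -> cyt_GLN + cyt_ADP + cyt_Pi	0	1000	nitrogen	OsGLN1-1 OR OsGLN1-2
chl_GOGAT	chl_GLN + chl_2OG + chl_NADPH -> 2 chl_GLU + chl_NADP	0	1000	nitrogen	OsNADH-GOGAT
cyt_SHMT	cyt_SER + cyt_THF -> cyt_GLY + cyt_METHF + cyt_H2O	0	1000	methyl-cycle	OsSHMT2
cyt_MTHFR	cyt_METHF + cyt_NADH -> cyt_5MTHF + cyt_NAD	0	1000	methyl-cycle	OsMTHFR
cyt_MS	cyt_HCY + cyt_5MTHF -> cyt_MET + cyt_THF	0	1000	methyl-cycle	OsMETS
cyt_SAMS	cyt_MET + cyt_ATP + cyt_H2O -> cyt_SAM + cyt_PPI + cyt_Pi	0	1000	methyl-cycle	OsSAMS1 OR OsSAMS2
cyt_AHC	cyt_AdoHcy + cyt_H2O -> cyt_HCY + cyt_ADN	0	1000	methyl-cycle	OsSAHH
cyt_ADK	cyt_ADN + cyt_ATP -> cyt_AMP + cyt_ADP	0	1000	salvage	
cyt_AK	cyt_AMP + cyt_ATP -> 2 cyt_ADP	0	1000	salvage	
cyt_PPase	cyt_PPI + cyt_H2O -> 2 cyt_Pi	0	1000	salvage	
cyt_PGDH	cyt_PGA + cyt_NAD -> cyt_3PHP + cyt_NADH	0	1000	serine	OsPGDH
cyt_PSAT	cyt_3PHP + cyt_GLU -> cyt_3PSER + cyt_2OG	0	1000	serine	OsPSAT
cyt_PSP	cyt_3PSER + cyt_H2O -> cyt_SER + cyt_Pi	0	1000	serine	OsPSP
mit_GDC	mit_GLY + mit_THF + mit_NAD -> mit_METHF + mit_NH3 + mit_CO2 + mit_NADH	0	1000	photorespiration	OsGLDC AND OsGCSH
mit_SHMT	mit_METHF + mit_GLY + mit_H2O -> mit_SER + mit_THF	0	1000	photorespiration	OsSHMT1
mit_AconHydr	mit_CIT -> mit_ACON + mit_H2O	0	1000	tca	OsACO1
mit_AconDHatase	mit_ACON + mit_H2O -> mit_ICIT	0	1000	tca	OsACO1
mit_ICDH	mit_ICIT + mit_NAD -> mit_2OG + mit_CO2 + mit_NADH	0	1000	tca	OsIDH
mit_ETC	mit_NADH + 2.5 cyt_ADP + 2.5 cyt_Pi -> mit_NAD + 2.5 cyt_ATP	0	1000	energy	
cyt_PDH	cyt_PYR + cyt_COA + cyt_NAD -> cyt_ACCOA + cyt_NADH + cyt_CO2	0	1000	tca	
cyt_CS	cyt_OAA + cyt_ACCOA + cyt_H2O -> cyt_CIT + cyt_COA	0	1000	tca	OsCSY
cyt_MDH	cyt_OAA + cyt_NADH <> cyt_MAL + cyt_NAD	-1000	1000	tca	OsMDH1
chl_RBC_carb	chl_RUBP + chl_CO2 + chl_H2O -> 2 chl_PGA	0	1000	calvin	OsRBCS AND OsRBCL
chl_RBC_oxy	chl_RUBP + chl_O2 -> chl_PGA + chl_PGLY	0	1000	photorespiration	OsRBCS AND OsRBCL
chl_PGK	chl_PGA + chl_ATP -> chl_DPGA + chl_ADP	0	1000	calvin	OsPGK
chl_GAPDH	chl_DPGA + chl_NADPH -> chl_GAP + chl_NADP + chl_Pi	0	1000	calvin	OsGAPA
chl_TPI	chl_GAP <> chl_DHAP	-1000	1000	calvin	
chl_ALD1	chl_GAP + chl_DHAP -> chl_FBP	0	1000	calvin	
chl_FBPase	chl_FBP + chl_H2O -> chl_F6P + chl_Pi	0	1000	calvin	OsFBP1
chl_TK1	chl_F6P + chl_GAP -> chl_X5P + chl_E4P	0	1000	calvin	OsTKL
chl_ALD2	chl_E4P + chl_DHAP -> chl_SBP	0	1000	calvin	
chl_SBPase	chl_SBP + chl_H2O -> chl_S7P + chl_Pi	0	1000	calvin	OsSBP
chl_TK2	chl_S7P + chl_GAP -> chl_X5P + chl_R5P	0	1000	calvin	OsTKL
chl_RPE	chl_X5P <> chl_RU5P	-1000	1000	calvin	
chl_RPI	chl_R5P <> chl_RU5P	-1000	1000	calvin	
chl_PRK	chl_RU5P + chl_ATP -> chl_RUBP + chl_ADP	0	1000	calvin	OsPRK
chl_ENO	chl_PGA -> chl_PEP + chl_H2O	0	1000	glycolysis	
chl_PEPC	chl_PEP + chl_CO2 + chl_H2O -> chl_OAA + chl_Pi	0	1000	anaplerosis	
chl_PK	chl_PEP + chl_ADP -> chl_PYR + chl_ATP	0	1000	glycolysis	
chl_MDH	chl_OAA + chl_NADPH -> chl_MAL + chl_NADP	0	1000	malate-valve	OsNADP-MDH
chl_PGP	chl_PGLY + chl_H2O -> chl_GLYC + chl_Pi	0	1000	photorespiration	OsPGLP
glycolate_tx	chl_GLYC -> per_GLYC	0	1000	photorespiration	
per_GOX	per_GLYC + per_O2 -> per_GLX + per_H2O2	0	1000	photorespiration	OsGLO1
per_CAT	2 per_H2O2 -> 2 per_H2O + per_O2	0	1000	photorespiration	OsCATA
per_SGAT_HPR	per_SER + per_GLX + per_NADH -> per_GLY + per_GLYCERATE + per_NAD	0	1000	photorespiration	OsAGT1 AND OsHPR1
per_MDH	per_MAL + per_NAD -> per_OAA + per_NADH	0	1000	photorespiration	OsPMDH
glycerate_tx	per_GLYCERATE -> chl_GLYCERATE	0	1000	photorespiration	
chl_GLYK	chl_GLYCERATE + chl_ATP -> chl_PGA + chl_ADP	0	1000	photorespiration	OsGLYK
photon_tx	x_Photon -> chl_PHOT	0	1000000	light	
chl_LightNonCyclic	8 chl_PHOT + 2 chl_H2O + 2 chl_NADP + 2.9 chl_ADP + 2.9 chl_Pi -> chl_O2 + 2 chl_NADPH + 2.9 chl_ATP	0	1000000	light	
chl_LightCyclic	2 chl_PHOT + chl_ADP + chl_Pi -> chl_ATP	0	1000000	light	
chl_ATPase	chl_ATP + chl_H2O -> chl_ADP + chl_Pi	0	1000	maintenance	
cyt_ATPase	cyt_ATP + cyt_H2O -> cyt_ADP + cyt_Pi	0	1000	maintenance	
cyt_NADHox	cyt_NADH + 0.5 cyt_O2 -> cyt_NAD + cyt_H2O	0	1000	maintenance	
NH_3__tx	x_Ammonia -> cyt_NH3	0	1000	nitrogen	OsAMT1-1 OR OsAMT1-2
ex_ammonia_tx	x_Ammonia -> chl_NH3	0	1000	nitrogen	
mit_am_tx	mit_NH3 -> chl_NH3	0	1000	nitrogen	
am_diff_tx	chl_NH3 -> cyt_NH3	0	0	nitrogen	
chl_MalOAA_tx	cyt_MAL + chl_OAA <> chl_MAL + cyt_OAA	-1000	1000	shuttle	
chl_MalGlu_tx	cyt_MAL + chl_GLU -> chl_MAL + cyt_GLU	0	1000	shuttle	
chl_Mal2OG_tx	cyt_2OG + chl_MAL -> chl_2OG + cyt_MAL	0	1000	shuttle	
chl_GluGln_tx	cyt_GLN + chl_GLU -> chl_GLN + cyt_GLU	0	1000	shuttle	
chl_SAM_T1	cyt_SAM -> chl_SAM	0	1000	shuttle	
chl_AdoHcy_T2	chl_AdoHcy -> cyt_AdoHcy	0	1000	shuttle	
chl_PGA_tx	chl_PGA -> cyt_PGA	0	1000	shuttle	
chl_Pyr_tx	chl_PYR -> cyt_PYR	0	1000	shuttle	
chl_Pi_tx	cyt_Pi <> chl_Pi	-1000	1000	shuttle	
mit_Gly_tx	cyt_GLY -> mit_GLY	0	1000	transport	
mit_Ser_tx	mit_SER -> cyt_SER	0	1000	transport	
mit_CIT_tx	cyt_CIT -> mit_CIT	0	1000	transport	
mit_2OG_tx	mit_2OG -> cyt_2OG	0	1000	transport	
mit_CO2_tx	mit_CO2 -> cyt_CO2	0	1000	transport	
mit_H2O_tx	cyt_H2O <> mit_H2O	-1000	1000	transport	
per_Ser_tx	cyt_SER -> per_SER	0	1000	transport	
per_Gly_tx	per_GLY -> cyt_GLY	0	1000	transport	
per_Mal_tx	cyt_MAL -> per_MAL	0	1000	transport	
per_OAA_tx	per_OAA -> cyt_OAA	0	1000	transport	
per_O2_tx	cyt_O2 -> per_O2	0	1000	transport	
per_H2O_tx	per_H2O <> cyt_H2O	-1000	1000	transport	
chl_CO2_tx	cyt_CO2 <> chl_CO2	-1000	1000	transport	
chl_O2_tx	chl_O2 <> cyt_O2	-1000	1000	transport	
chl_H2O_tx	cyt_H2O <> chl_H2O	-1000	1000	transport	
CO2_tx	x_CO2 <> cyt_CO2	-1000	1000	exchange	
O2_tx	cyt_O2 <> x_O2	-1000	1000	exchange	
H2O_tx	x_H2O <> cyt_H2O	-1000	1000	exchange	
Pi_tx	x_Pi <> cyt_Pi	-1000	1000	exchange	
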