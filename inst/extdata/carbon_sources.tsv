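source	formula	carbons	entry_point	exchange_id	supported	notes
glycerol	C3H8O3	3	glyceraldehyde	EX_glyc_e	TRUE	passive uptake, no ATP cost
propanol	C3H8O	3	succinyl-CoA	NA	FALSE	degradation route not curated
raffinose	C18H32O16	18	glucose/galactose	EX_raf_e	TRUE	ABC import, hydrolysed to glc+gal+fru
n_acetyl_glutamate	C7H11NO5	7	acetyl-CoA	NA	FALSE	degradation route not curated
melibiose	C12H22O11	12	glucose/galactose	EX_mel_e	TRUE
lactose	C12H22O11	12	glucose/galactose	EX_lac2_e	TRUE
glutamate	C5H9NO4	5	2-oxoglutarate	EX_glu_e	TRUE
trehalose	C12H22O11	12	glucose/galactose	EX_tre_e	TRUE
maltose	C12H22O11	12	glucose/galactose	EX_malt_e	TRUE
maltodextrin	NA	18	glucose/galactose	EX_mdx_e	TRUE	maltotriose unit
sucrose	C12H22O11	12	glucose/galactose	EX_suc_e	TRUE
cellulose	NA	12	glucose/galactose	EX_cellu_e	TRUE	cellobiose unit
cellobiose	C12H22O11	12	glucose/galactose	EX_cel_e	TRUE
xylose	C5H10O5	5	2-oxoglutarate	EX_xyl_e	TRUE	oxidative route, 2 NADPH per pentose
xylan	NA	5	2-oxoglutarate	EX_xylan_e	TRUE	xylose unit
d_arabinose	C5H10O5	5	2-oxoglutarate	EX_ara_e	TRUE	oxidative route, 2 NADPH per pentose
arabinan	NA	5	2-oxoglutarate	EX_aran_e	TRUE	arabinose unit
mannose	C6H12O6	6	glucose/galactose	EX_man_e	TRUE	isomerized to fructose/glucose
galactose	C6H12O6	6	glucose/galactose	EX_gal_e	TRUE	oxidized by the promiscuous glucose dehydrogenase
glycogen	NA	6	glucose/galactose	NA	FALSE	intracellular storage; external feed not modeled
glucose	C6H12O6	6	glucose/galactose	EX_glc_e	TRUE	reference source
dextrin	NA	6	glucose/galactose	EX_dex_e	TRUE	glucose-equivalent unit
fructose	C6H12O6	6	glucose/galactose	EX_fru_e	TRUE
succinate	C4H6O4	4	succinate	EX_succ_e	TRUE
citrate	C6H8O7	6	TCA cycle	EX_cit_e	TRUE
lactate	C3H6O3	3	acetyl-CoA	EX_lact_e	TRUE
alanine	C3H7NO2	3	2-oxoglutarate	EX_ala_e	TRUE	paper groups alanine with the 2-oxoglutarate entries; route runs via pyruvate
l_arabinose	C5H10O5	5	malate	NA	FALSE	malate-entry route not curated (optional pentose malate route is off by default)
malate	C4H6O5	4	malate	EX_mal_e	TRUE
acetoin	C4H8O2	4	acetyl-CoA	NA	FALSE	degradation route not curated
pyruvate	C3H4O3	3	acetyl-CoA	EX_pyr_e	TRUE
tartrate	C4H6O6	4	oxaloacetate	NA	FALSE	degradation route not curated
ethanol	C2H6O	2	acetyl-CoA	EX_etoh_e	TRUE
phenol	C6H6O	6	acetyl-CoA	EX_phenol_e	TRUE
cytosine	C4H5N3O	4	2-oxoglutarate	NA	FALSE	degradation route not curated
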