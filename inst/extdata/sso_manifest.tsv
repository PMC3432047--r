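figure	index	enzyme	reaction_ids	gene	note
2	1	glucose 1-dehydrogenase	R_gdh	SSOg01	promiscuous glucose/galactose dehydrogenase; shares gene with index 19
2	2	gluconolactonase	R_gnl	SSOg02
2	3	gluconate dehydratase	R_gad	SSOg03
2	4	2-dehydro-3-deoxygluconokinase	R_kdgk	SSOg04	semi-phosphorylative branch
2	5	2-dehydro-3-deoxy-phosphogluconate aldolase	R_kdpga	SSOg05	shares gene with index 21 (one bifunctional aldolase)
2	6	glyceraldehyde-3-phosphate dehydrogenase (non-phosphorylating)	R_gapn	SSOg06	catabolic GAPN; makes both ED branches energetically equivalent
2	7	phosphoglycerate mutase	R_pgm	SSOg07
2	8	phosphopyruvate hydratase	R_eno	SSOg08	enolase
2	9	pyruvate kinase	R_pk	SSOg09
2	10	pyruvate synthase	R_pyrs	SSOg10	reversible (pyruvate:ferredoxin oxidoreductase); carboxylating direction used in autotrophy
2	11	citrate (Si)-synthase	R_cs	SSOg11
2	12	aconitate hydratase	R_aco	SSOg12	the two hydration half-reactions are merged into one reaction
2	13	isocitrate dehydrogenase	R_icdh	SSOg13
2	14	2-oxoglutarate synthase	R_ogor	SSOg14
2	15	succinate-CoA ligase	R_scl	SSOg15	ADP-forming, reversible
2	16	succinate dehydrogenase	R_sdh	SSOg16	FAD-linked; electrons enter the lumped ETC at P/O 0.5
2	17	fumarate hydratase	R_fum	SSOg17
2	18	malate dehydrogenase	R_mdh	SSOg18
2	19	glucose 1-dehydrogenase (galactose)	R_galdh	SSOg01	same gene as index 1
2	20	galactonate dehydratase	R_gald	SSOg20	2-keto-3-deoxy-galactonate pooled with KDG (enzyme promiscuity)
2	21	2-keto-3-deoxygluconate aldolase	R_kdga	SSOg05	same gene as index 5
2	22	aldehyde dehydrogenase	R_aldh	SSOg22	glyceraldehyde -> glycerate
2	23	glycerate kinase	R_glyk	SSOg23
2	24	malate dehydrogenase (decarboxylating)	R_mae	SSOg24	malic enzyme
2	25	phosphoenolpyruvate carboxykinase (GTP)	R_pepck	SSOg25
2	26	phosphoenolpyruvate carboxylase	R_pepc	SSOg26
2	27	pyruvate carboxylase	R_pc	SSOg27
2	28	triose-phosphate isomerase	R_tpi	SSOg28
2	29	fructose-bisphosphate aldolase	R_fba	SSOg29
2	30	fructose-bisphosphatase	R_fbp	SSOg30
2	31	glucose-6-phosphate isomerase	R_pgi	SSOg31
2	32	beta-phosphoglucomutase	R_pgmt	SSOg32
2	33	glucose-1-phosphate adenylyltransferase	R_agpt	SSOg33
2	34	starch synthase	R_glgs	SSOg34	glycogen synthase
2	35	glucan 1,4-alpha-glucosidase	R_amyl	SSOg35
2	36	6-phospho-3-hexuloisomerase	R_phi	SSOg36	reverse ribulose monophosphate pathway
2	37	3-hexulose-6-phosphate synthase	R_hps	SSOg37	pentose provision releases formaldehyde (oxidized to formate, reused in the C1 pool)
2	38	ribose-5-phosphate isomerase	R_rpi	SSOg38
2	39	ribose-phosphate diphosphokinase	R_prps	SSOg39	PRPP synthetase
2	40	transketolase	R_tkt2	SSOg40	sedoheptulose-7-phosphate-forming; no transaldolase exists, so S7P is exported
2	41	transketolase	R_tkt1	SSOg40	same gene as index 40; supplies xylulose 5-phosphate and erythrose 4-phosphate
2	42	sulfite reductase	R_sir	SSOg42	reversible; sulfide oxidation direction is the autotrophic electron source
2	43	phosphoadenylyl-sulfate reductase	R_papr	SSOg43
2	44	sulfate adenylyltransferase	R_sat	SSOg44
2	45	adenylyl-sulfate kinase	R_apsk	SSOg45
2	46	3'(2'),5'-bisphosphate nucleotidase	R_bpnt	SSOg46
2	47	phosphoglycerate kinase	R_pgk	SSOg47	gluconeogenic direction only (ATP-consuming irreversibility convention)
2	48	glyceraldehyde-3-phosphate dehydrogenase (phosphorylating)	R_gapdh	SSOg48	gluconeogenic direction only
6	49	phenol 2-monooxygenase	R_pmo	SSOg49
6	50	catechol 2,3-dioxygenase	R_c23d	SSOg50	meta-cleavage
6	51	2-hydroxymuconate-semialdehyde hydrolase	R_hmsh	SSOg51	releases formate
6	52	2-oxopent-4-enoate hydratase	R_opeh	SSOg52
6	53	4-hydroxy-2-ketovalerate aldolase	R_hkva	SSOg53
6	54	aldehyde dehydrogenase	R_aldd	SSOg54	acetaldehyde -> acetate; also used for ethanol catabolism
6	55	acetate-CoA ligase	R_acs	SSOg55	AMP-forming
3	1	acetyl-CoA C-acetyltransferase	R_acat	SSOhb01
3	2	acetyl-CoA carboxylase	R_acc	SSOhb02a,SSOhb02b	two-subunit complex (AND association)
3	3	malonyl-CoA reductase (NADPH)	R_mcr	SSOhb03
3	4	malonic semialdehyde reductase (NADPH)	R_msr	SSOhb04
3	5	3-hydroxypropionate-CoA ligase	R_hpcl	SSOhb05	modeled ADP-forming (one ATP equivalent)
3	6	3-hydroxypropionyl-CoA dehydratase	R_hpcd	SSOhb06
3	7	acryloyl-CoA reductase (NADPH)	R_acrr	SSOhb07
3	8	propionyl-CoA carboxylase	R_pcc	SSOhb08
3	9	methylmalonyl-CoA epimerase	R_mce	SSOhb09
3	10	methylmalonyl-CoA mutase	R_mcm	SSOhb10
3	11	succinyl-CoA reductase	R_scr	SSOhb11
3	12	succinic semialdehyde reductase (NADPH)	R_ssr	SSOhb12
3	13	4-hydroxybutyrate-CoA ligase	R_hbcl	SSOhb13	modeled ADP-forming (one ATP equivalent)
3	14	4-hydroxybutyryl-CoA dehydratase	R_hbcd	SSOhb14
3	15	enoyl-CoA hydratase	R_ech	SSOhb15
3	16	(S)-3-hydroxybutyryl-CoA dehydrogenase (NAD+)	R_hbd	SSOhb16
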