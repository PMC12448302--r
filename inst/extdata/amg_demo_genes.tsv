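contig	gene_id	idx	start	end	strand	is_viral_like	is_candidate_amg	is_lysogeny_marker	is_trna	function_id	bit_score	auxiliary_score	denylist_category
ctg_demo	g01	1	1	2400	+	FALSE	TRUE	FALSE	FALSE	K15633	82.4	1	none
ctg_demo	g02	2	2501	4900	+	TRUE	FALSE	FALSE	FALSE	phage_portal	210.0	1	none
ctg_demo	g03	3	5001	7400	-	TRUE	FALSE	FALSE	FALSE	phage_terminase	305.2	1	none
ctg_demo	g04	4	7501	9900	+	FALSE	TRUE	FALSE	FALSE	K00058	70.1	2	none
ctg_demo	g05	5	10001	12400	+	TRUE	FALSE	FALSE	FALSE	phage_capsid	188.9	1	none
ctg_demo	g06	6	12501	14900	-	TRUE	FALSE	FALSE	FALSE	phage_tail_fiber	150.6	1	none
ctg_demo	g07	7	15001	17400	+	FALSE	TRUE	FALSE	FALSE	K01610	71.5	4	none
ctg_demo	g08	8	17501	19900	+	TRUE	FALSE	FALSE	FALSE	phage_baseplate	133.0	1	none
ctg_demo	g09	9	20001	22400	+	FALSE	TRUE	FALSE	FALSE	K02906	95.0	2	ribosomal proteins
ctg_demo	g10	10	22501	24900	-	FALSE	FALSE	FALSE	FALSE	hypothetical	40.2	3	none
ctg_demo	g11	11	25001	27400	+	TRUE	FALSE	FALSE	FALSE	phage_holin	98.7	1	none
ctg_demo	g12	12	27501	29900	+	FALSE	TRUE	FALSE	FALSE	K00390	66.3	3	none
ctg_demo	g13	13	30001	32400	+	TRUE	FALSE	FALSE	FALSE	phage_major_capsid	244.8	1	none
ctg_demo	g14	14	32501	34900	-	FALSE	FALSE	FALSE	FALSE	hypothetical	35.9	3	none
ctg_demo	g15	15	35001	37400	+	FALSE	TRUE	FALSE	FALSE	K01624	88.0	2	none
ctg_demo	g16	16	37501	39900	+	FALSE	FALSE	FALSE	FALSE	hypothetical	42.1	3	none
ctg_demo	g17	17	40001	42400	+	FALSE	FALSE	FALSE	FALSE	hypothetical	51.3	3	none
ctg_demo	g18	18	42501	44900	-	FALSE	FALSE	FALSE	FALSE	hypothetical	47.7	3	none
ctg_demo	g19	19	45001	47400	+	FALSE	FALSE	FALSE	FALSE	hypothetical	39.4	3	none
ctg_demo	g20	20	47501	49900	+	TRUE	FALSE	FALSE	FALSE	phage_tail_sheath	120.5	1	none
ctg_demo	g21	21	50001	52400	+	TRUE	FALSE	FALSE	FALSE	phage_lysin	101.8	1	none
ctg_demo	g22	22	52501	54900	+	FALSE	TRUE	FALSE	FALSE	K01915	75.2	2	none
ctg_demo	g23	23	55001	57400	+	FALSE	FALSE	FALSE	TRUE	tRNA-Leu	55.0	1	none
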