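clade	total_nodes	pct_concordant	pct_discordant	pct_strong_discordance	pct_weak_mt_strong_nuc	pct_strong_mt_weak_nuc	pct_weak_both	pct_strong_resolved_mt	binomial_P	shared_combined_mt	shared_combined_nuc	shared_mt_nuc	nuc_variable	mt_variable	nuc_ci	nuc_ri	mt_ci	mt_ri
Balistid fish	23	39	61	14	43	21	21	50	0.5000	16	24	11	341	337	0.5851	0.7298	0.4175	0.5380
Scarine fish	40	55	45	44	22	17	17	75	0.1094	83	63	50	612	743	0.5579	0.7874	0.3805	0.6012
Hemiphractid frogs	40	45	55	36	18	23	23	75	0.1094	64	52	30	441	1344	0.6427	0.8552	0.3065	0.4589
Hylid frogs	76	54	46	17	29	9	46	67	0.2344	27	44	13	715	1442	0.2844	0.5646	0.1486	0.3135
Plethodon salamanders	51	33	67	56	21	24	0	79	0.0074	73	27	23	1204	1400	0.6042	0.8132	0.3069	0.6329
Phrynosomatid lizards	35	49	51	28	44	17	11	0	0.0313	37	71	26	1155	2258	0.5498	0.7490	0.3327	0.3284
Alcid birds	21	67	33	29	14	43	14	100	0.2500	91	33	23	255	1559	0.6471	0.7918	0.4129	0.5823
Caprimulgid birds	55	56	44	17	4	33	46	50	0.3750	53	82	38	790	522	0.4708	0.7560	0.2216	0.5078
Cotingid birds	35	63	37	23	31	0	46	67	0.3750	53	71	35	440	493	0.5858	0.7162	0.2300	0.3154
Dicaeid birds	28	36	64	17	11	39	33	33	0.3750	80	34	24	86	660	0.8043	0.9455	0.7067	0.3793
Emydid turtles	36	33	67	29	33	17	21	38	0.2734	54	60	37	477	460	0.6581	0.8662	0.4591	0.7820
Cervid mammals	23	30	70	19	0	56	25	67	0.3750	99	37	27	127	624	0.7414	0.9085	0.3097	0.4704
Murid rodents (Philippines)	55	58	42	9	43	13	35	50	0.5000	30	63	23	640	628	0.4179	0.6474	0.1649	0.3342
Murid rodents (Sahul)	60	70	30	39	22	17	22	0	0.0078	55	96	53	4226	1175	0.5094	0.7129	0.1666	0.2974
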