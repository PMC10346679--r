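environment	timepoint	trait	p1_mean	p1_sd	p2_mean	p2_sd	f1_mean	f1_sd	mph_printed	mph_flag	hph_printed	hph_flag	note
early_rice	1DPA	leaf_length_cm	28.17	1.485	25.2	1.92	30.4	2.32	13.9	*	7.9		
early_rice	1DPA	leaf_width_cm	2.02	0.107	2.18	0.33	2.38	0.30	13.3	*	9.1	*	
early_rice	1DPA	leaf_area_cm2	42.68	NA	41.2	NA	54.26	NA	29.3	**	27.1	**	
early_rice	1DPA	spikelet_weight_g	6.7	NA	5.68	NA	7.3	NA	17.9	**	8.9		
early_rice	10DPA	leaf_length_cm	31.8	3.585	30.15	1.80	30.18	1.29	-2.6		-5		
early_rice	10DPA	leaf_width_cm	2.07	0.080	2.33	0.22	2.35	0.28	6.8		0.8		
early_rice	10DPA	leaf_area_cm2	49.37	NA	52.69	NA	53.19	NA	4.2		0.1		printed HPH inconsistent with printed means (recomputed 0.95)
early_rice	10DPA	tgw_g	24.86	NA	14.77	NA	20.42	NA	2.81		-17.8	**	printed MPH inconsistent with printed means (recomputed 3.05)
middle_rice	1DPA	leaf_length_cm	27	NA	38.5	NA	44.1	NA	34.7	**	14.5		
middle_rice	1DPA	leaf_width_cm	1.93	NA	2	NA	2.1	NA	6.9		5		
middle_rice	1DPA	leaf_area_cm2	39.08	NA	57.75	NA	69.46	NA	43.4	**	20.2	**	
middle_rice	1DPA	spikelet_weight_g	5.03	NA	4.25	NA	4.84	NA	4.3		-3.7		
middle_rice	10DPA	leaf_length_cm	31.37	NA	40.78	NA	43.68	NA	21.1	**	7.1		
middle_rice	10DPA	leaf_width_cm	2.11	NA	2.22	NA	2.28	NA	5.3		2.7		
middle_rice	10DPA	leaf_area_cm2	49.64	NA	67.9	NA	74.69	NA	27.1	**	10		
middle_rice	10DPA	tgw_g	29.06	NA	14.64	NA	21.1	NA	-3.4		-27.3	**	
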