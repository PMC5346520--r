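problem	rank	region	side	weight_abs	n_features
case	1	Putamen	R	0.008225	693
case	2	Amygdala	R	0.006528	248
case	3	Middle frontal gyrus, orbital	R	0.005307	915
case	4	Middle frontal gyrus	R	0.004982	3811
case	5	Putamen	L	0.004955	652
case	6	Nucleus caudate	R	0.004718	922
case	7	Superior frontal gyrus, orbital	R	0.004607	943
case	8	Inferior frontal gyrus, pars opercularis	R	0.004562	1074
case	9	Amygdala	L	0.004442	220
case	10	Middle frontal gyrus	L	0.004413	3307
case	11	Superior frontal gyrus	L	0.003974	2389
case	12	Superior frontal gyrus	R	0.003886	2806
case	13	Anterior cingulate gyrus	L	0.003604	1396
case	14	Nucleus caudate	L	0.003440	857
case	15	Inferior frontal gyrus, pars triangularis	R	0.003423	1563
case	16	Hippocampus	L	0.003387	918
case	17	Inferior frontal gyrus, pars opercularis	L	0.003373	800
case	18	Hippocampus	R	0.003352	944
case	19	Inferior frontal gyrus, orbital	R	0.003259	1511
case	20	Inferior frontal gyrus, pars triangularis	L	0.002973	1829
case	21	Superior medial frontal gyrus	R	0.002962	1676
case	22	Middle frontal gyrus, orbital	L	0.002909	758
case	23	Anterior cingulate gyrus	R	0.002835	1304
case	24	Thalamus	L	0.002756	628
case	25	Superior medial frontal gyrus	L	0.002705	2273
case	26	Inferior frontal gyrus, orbital	L	0.002517	1520
case	27	Superior frontal gyrus, orbital	L	0.002093	931
case	28	Medial frontal gyrus, orbital	R	0.002088	823
case	29	Thalamus	R	0.001953	724
case	30	Medial frontal gyrus, orbital	L	0.001491	653
disorder	1	Superior frontal gyrus	L	0.005132	2426
disorder	2	Middle frontal gyrus	R	0.005091	3906
disorder	3	Inferior frontal gyrus, pars triangularis	R	0.005011	1593
disorder	4	Inferior frontal gyrus, pars opercularis	R	0.004954	1077
disorder	5	Nucleus caudate	R	0.004559	934
disorder	6	Inferior frontal gyrus, pars triangularis	L	0.004533	1858
disorder	7	Superior frontal gyrus	R	0.004340	1691
disorder	8	Middle frontal gyrus	L	0.004138	3344
disorder	9	Superior medial frontal gyrus	L	0.004030	2287
disorder	10	Superior frontal gyrus	L	0.003939	2898
disorder	11	Inferior frontal gyrus, orbital	R	0.003661	1523
disorder	12	Middle frontal gyrus, orbital	L	0.003616	762
disorder	13	Amygdala	R	0.003056	248
disorder	14	Inferior frontal gyrus, orbital	L	0.003012	1529
disorder	15	Inferior frontal gyrus, pars opercularis	L	0.002931	806
disorder	16	Anterior cingulate gyrus	R	0.002812	1307
disorder	17	Medial frontal gyrus, orbital	R	0.002793	929
disorder	18	Superior frontal gyrus, orbital	L	0.002753	934
disorder	19	Amygdala	L	0.002355	220
disorder	20	Putamen	R	0.002345	811
disorder	21	Nucleus caudate	L	0.002193	868
disorder	22	Hippocampus	L	0.002095	918
disorder	23	Anterior cingulate gyrus	L	0.001897	1396
disorder	24	Superior frontal gyrus, orbital	R	0.001869	954
disorder	25	Medial frontal gyrus, orbital	L	0.001861	662
disorder	26	Medial frontal gyrus, orbital	R	0.001810	824
disorder	27	Putamen	L	0.001670	706
disorder	28	Hippocampus	R	0.001664	945
disorder	29	Thalamus	L	0.001555	628
disorder	30	Thalamus	R	0.001193	765
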