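gene	s001	s002	s003	s004	s005	s006	s007	s008	s009	s010	s011	s012
gene_01	1.2465	0.5496	-1.5244	-0.2562	0.6369	1.3611	-0.2189	-0.9911	-0.6055	-0.8716	-1.0502	0.3292
gene_02	1.0569	-0.251	-0.1487	0.1069	0.1462	1.1154	-0.1464	-0.2561	-1.3226	-0.4843	-1.7222	0.5918
gene_03	1.0308	0.2086	-0.346	-0.0049	0.662	1.1611	0.6971	0.7456	-1.6241	-0.9524	-1.3613	0.7133
gene_04	1.1623	1.2677	-0.3389	-0.5254	0.7604	0.7152	0.1844	-0.7392	-0.7121	-1.1134	-1.0687	0.4078
gene_05	1.5781	0.7968	0.1375	-0.1152	1.7597	1.1069	-0.3886	0.1972	-0.8881	-1.9328	-1.0116	-0.1046
gene_06	1.0127	0.4547	-0.0117	-0.3279	1.6618	1.461	0.0284	-0.1075	-1.6443	-0.5769	-1.1281	-0.343
gene_07	0.9486	0.9057	-0.1768	-0.3028	0.9329	1.5191	-0.0538	-0.3415	-1.4096	-0.7096	-1.266	-0.4785
gene_08	0.3756	-0.0922	-0.1101	0.3103	2.005	1.355	0.9359	-0.0596	-1.6539	-0.846	-1.5917	0.9254
gene_09	-0.5617	-1.1378	-1.2934	1.1248	-0.701	-0.0289	-0.625	-1.8304	1.9048	0.5299	-0.2648	0.9071
gene_10	-0.2653	-0.3286	-1.3037	-0.1973	-0.7114	0.0288	-1.0735	-1.0918	-0.569	0.5196	-0.9702	0.1335
gene_11	-0.6497	0.0367	1.6908	-0.843	-1.2008	0.5281	0.3261	-0.2999	0.5517	-1.2465	-0.7965	1.7433
gene_12	0.8641	0.7312	1.7352	0.1384	0.8721	1.0502	-1.1374	-0.0437	2.3935	1.2444	-0.7672	-2.9515
gene_13	0.3292	-0.3058	-0.7125	0.2922	1.7389	-0.0026	-0.0045	1.562	-0.3805	-0.6329	0.137	-1.7253
gene_14	1.2229	2.196	-0.3685	0.9259	-0.4895	0.2076	0.3981	1.156	1.2421	0.1659	0.7152	-0.3784
gene_15	0.6955	0.2546	0.67	-0.6649	-0.3753	0.7522	0.9966	-0.3603	-0.6701	0.4785	-0.5887	-1.0452
gene_16	0.5553	1.0655	1.2876	0.5835	1.2641	0.4884	2.2965	-1.8132	0.0022	0.4754	-0.7777	0.2054
gene_17	1.0225	-1.0101	-0.7519	0.1442	0.8806	0.4314	-0.6909	0.5593	-0.5638	-2.7423	0.6427	0.3992
gene_18	0.6987	0.5225	-0.5965	1.0796	-0.6521	1.4955	0.1344	-0.0735	0.0263	0.2393	-0.0846	0.459
gene_19	-0.2559	0.616	1.3471	0.6758	-0.2197	-0.3729	-0.032	0.0873	-0.0636	-0.5157	0.0781	-0.9167
gene_20	0.2175	1.0917	1.365	1.1342	-0.9102	1.8917	-0.5647	0.2578	-1.122	0.1531	1.7291	0.1724
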