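id	study	domain	stimuli	n_ppt	n_trials	brt	se_brt	p_brt	bacc	se_bacc	p_bacc	bacc_bayes	bf_label
1	Hare et al.	Preferential	Abstract	19	570	-0.022	0.014	0.112	-0.199	0.133	0.135	-0.169	Anecdotal evidence for H0
2	Pirrone et al.	Preferential	Abstract	21	42826	-0.025	0.008	0.007	-0.092	0.049	0.062	-0.096	Anecdotal evidence for H0
3	Konovalov and Krajbich	Preferential	Abstract	45	5609	-0.07	0.012	<0.001	0.03	0.064	0.638	0.026	Moderate evidence for H0
4	Shevlin et al.	Preferential	Abstract	52	14383	-0.077	0.007	<0.001	0.068	0.026	0.009	0.067	Anecdotal evidence for H1
5	Shevlin et al.	Preferential	Abstract	70	18406	-0.039	0.005	<0.001	0.149	0.05	0.003	0.136	Moderate evidence for H1
6	Pirrone et al.	Perceptual	Brightness	9	12600	-0.008	0.011	0.5	-0.497	0.051	<0.001	-0.507	Extreme evidence for H1
7	Ko et al.	Perceptual	Brightness	35	33755	-0.015	0.005	0.003	-0.325	0.029	<0.001	-0.328	Extreme evidence for H1
8	Teodorescu et al.	Perceptual	Brightness	7	8400	-0.037	0.011	0.009	-0.305	0.063	<0.001	-0.307	Strong evidence for H1
9	Teodorescu et al.	Perceptual	Brightness	7	8398	-0.034	0.005	<0.001	-0.269	0.035	<0.001	-0.263	Very strong evidence for H1
10	Ko et al.	Perceptual	brightness	37	35562	-0.008	0.004	0.082	-0.252	0.028	<0.001	-0.254	Extreme evidence for H1
11	Turner et al.	Perceptual	Brightness	30	25931	-0.01	0.004	0.007	-0.23	0.028	<0.001	-0.234	Extreme evidence for H1
12	Ting and Gluth	Perceptual	Brightness	61	11514	-0.053	0.007	<0.001	0.056	0.028	0.044	0.045	Moderate evidence for H0
13	Edmunds et al.	Preferential	Numbers	56	2232	0.001	0.011	0.922	-0.149	0.052	0.004	-0.169	Strong evidence for H1
14	Shevlin et al.	Preferential	Numbers	75	19198	0.015	0.009	0.099	-0.13	0.036	<0.001	-0.139	Very strong evidence for H1
15	Glickman et al.	Perceptual	Numbers	27	13361	-0.035	0.004	<0.001	-0.024	0.03	0.427	-0.018	Moderate evidence for H0
16	Glickman et al.	Perceptual	Numbers	30	13401	-0.013	0.003	<0.001	-0.012	0.024	0.607	-0.012	Strong evidence for H0
17	Pirrone	Preferential	Numbers	62	27900	0.013	0.007	0.057	0.029	0.034	0.398	0.028	Moderate evidence for H0
18	Lee et al.	Perceptual	Numbers	44	8662	-0.03	0.007	<0.001	0.036	0.031	0.25	0.039	Moderate evidence for H0
19	Edmunds et al.	Preferential	Numbers	54	1753	0.008	0.008	0.315	0.12	0.055	0.028	0.118	Anecdotal evidence for H1
20	Oud et al.	Preferential	Preference	49	8955	-0.059	0.01	<0.001	-0.296	0.151	0.05	-0.286	Anecdotal evidence for H1
21	Sepulveda et al.	Preferential	Preference	31	3720	0.047	0.015	0.005	-0.283	0.058	<0.001	-0.250	Extreme evidence for H1
22	Folke et al.	Preferential	Preference	28	6720	-0.001	0.025	0.982	-0.281	0.119	0.018	-0.227	Anecdotal evidence for H1
23	Eum et al.	Preferential	Preference	50	19000	-0.041	0.005	<0.001	-0.048	0.041	0.247	-0.045	Moderate evidence for H0
24	Smith and Krajbich	Preferential	Preference	42	4013	-0.029	0.009	0.004	-0.025	0.048	0.609	-0.022	Moderate evidence for H0
25	Pirrone	Preferential	Preference	66	13200	-0.056	0.008	<0.001	-0.0001	0.038	0.997	0.009	Moderate evidence for H0
26	Smith and Krajbich	Preferential	Preference	44	6453	-0.071	0.01	<0.001	0.017	0.046	0.704	0.023	Moderate evidence for H0
27	Smith and Krajbich	Preferential	Preference	36	7200	-0.035	0.011	0.004	0.02	0.047	0.666	0.021	Moderate evidence for H0
28	Brus et al.	Preferential	Preference	33	5016	-0.052	0.016	0.002	0.026	0.047	0.584	0.028	Moderate evidence for H0
29	Smith et al.	Preferential	Preference	27	2850	-0.12	0.014	<0.001	0.042	0.074	0.565	0.060	Moderate evidence for H0
30	Smith and Krajbich	Preferential	Preference	42	3995	-0.036	0.01	<0.001	0.051	0.05	0.313	0.053	Moderate evidence for H0
31	Krajbich et al.	Preferential	Preference	39	3647	-0.061	0.012	<0.001	0.057	0.054	0.294	0.061	Moderate evidence for H0
32	Shevlin et al.	Preferential	Preference	44	10577	-0.034	0.008	<0.001	0.063	0.034	0.066	0.067	Anecdotal evidence for H0
33	Ting and Gluth	Preferential	Preference	61	11526	-0.068	0.01	<0.001	0.069	0.024	0.004	0.071	Moderate evidence for H1
34	Lee and Daunizeau	Preferential	Preference	41	3034	-0.088	0.012	<0.001	0.079	0.058	0.178	0.081	Anecdotal evidence for H0
35	Edmunds et al.	Preferential	Preference	41	3698	-0.067	0.012	<0.001	0.088	0.072	0.223	0.066	Moderate evidence for H0
36	Chen and Krajbich	Preferential	Preference	44	8453	-0.053	0.007	<0.001	0.107	0.047	0.023	0.112	Anecdotal evidence for H1
37	Edmunds et al.	Preferential	Preference	52	2599	-0.029	0.01	0.004	0.116	0.065	0.075	0.129	Anecdotal evidence for H0
38	Smith and Krajbich	Peferential	Preference	44	7236	-0.044	0.008	<0.001	0.127	0.047	0.007	0.126	Anecdotal evidence for H1
39	Gwinn	Preferential	Preference	36	6237	-0.03	0.012	0.02	0.156	0.073	0.033	0.161	Anecdotal evidence for H1
40	Shevlin et al.	Preferential	Preference	50	12931	-0.027	0.006	<0.001	0.21	0.046	<0.001	0.211	Extreme evidence for H1
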