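gene	F1_S01	F1_S02	F1_S03	F1_S04	F1_S05	F1_S06	F1_S07	F1_S08	F1_S09	F1_S10
G001	8.974	8.974	8.974	9.197	9.197	10.366	8.658	8.766	9.360	9.005
G002	9.291	9.291	9.291	8.338	8.338	9.873	10.413	9.276	9.051	9.104
G003	2.878	2.878	2.878	4.803	4.803	3.295	4.314	3.401	4.640	4.062
G004	9.012	9.012	9.012	9.031	9.031	9.749	7.976	8.751	8.766	8.896
G005	6.622	6.622	6.622	7.129	7.129	8.098	7.079	8.562	7.002	7.451
G006	6.517	6.517	6.517	6.274	6.274	6.812	6.750	8.091	7.769	5.973
G007	8.457	8.457	8.457	7.426	7.426	6.563	7.553	7.032	7.469	6.353
G008	3.905	3.905	3.905	3.372	3.372	2.622	2.459	3.466	2.700	1.926
G009	6.769	6.769	6.769	7.492	7.492	7.764	7.378	8.367	6.019	6.080
G010	8.045	8.045	8.045	7.418	7.418	7.676	8.432	7.484	7.609	8.250
G011	4.288	4.288	4.288	4.593	4.593	5.940	5.603	5.487	6.374	5.467
G012	7.125	7.125	7.125	8.314	8.314	9.721	6.643	7.509	6.096	7.969
G013	8.796	8.796	8.796	9.920	9.920	8.822	8.432	9.955	9.277	8.230
G014	2.112	2.112	2.112	3.374	3.374	2.352	3.428	5.161	3.098	3.615
G015	5.727	5.727	5.727	4.422	4.422	5.917	5.276	6.248	6.852	6.148
G016	9.685	9.685	9.685	9.684	9.684	8.970	9.503	9.776	10.606	9.377
G017	9.537	9.537	9.537	9.550	9.550	10.183	10.362	9.585	10.094	9.734
G018	3.547	3.547	3.547	3.142	3.142	2.290	2.592	3.339	4.083	2.882
G019	5.219	5.219	5.219	4.765	4.765	7.570	4.909	5.360	5.106	6.769
G020	5.388	5.388	5.388	5.716	5.716	6.384	6.969	6.260	7.244	5.991
G021	9.578	9.578	9.578	10.101	10.101	8.850	9.452	10.109	8.764	9.773
G022	2.461	2.461	2.461	3.433	3.433	2.977	4.036	3.464	3.367	3.829
G023	11.066	11.066	11.066	10.380	10.380	10.601	8.565	10.104	9.671	8.960
G024	9.228	9.228	9.228	11.025	11.025	9.651	9.643	9.369	9.350	9.670
G025	3.185	3.185	3.185	2.763	2.763	1.360	3.743	3.405	3.097	2.651
G026	6.372	6.372	6.372	4.513	4.513	6.110	6.693	7.182	5.071	6.937
G027	4.495	4.495	4.495	5.389	5.389	5.730	4.456	4.427	4.921	5.854
G028	10.507	10.507	10.507	10.183	10.183	9.277	9.832	9.290	9.383	9.244
G029	6.090	6.090	6.090	7.224	7.224	6.164	4.878	5.615	5.253	5.685
G030	8.760	8.760	8.760	7.587	7.587	8.571	8.325	8.225	8.772	8.112
G031	8.122	8.122	8.122	6.980	6.980	7.855	8.851	7.102	7.646	7.743
G032	9.031	9.031	9.031	7.923	7.923	8.874	8.256	8.486	9.783	7.665
G033	5.177	5.177	5.177	4.262	4.262	5.899	5.768	5.629	5.676	4.331
G034	5.087	5.087	5.087	6.964	6.964	6.484	7.248	8.662	9.854	6.504
G035	2.260	2.260	2.260	1.884	1.884	2.005	0.771	0.505	1.396	2.701
G036	8.369	8.369	8.369	7.702	7.702	8.606	7.984	8.101	9.314	9.555
G037	2.207	2.207	2.207	3.689	3.689	1.452	1.188	1.810	3.737	1.729
G038	4.126	4.126	4.126	3.747	3.747	2.834	3.274	2.330	3.902	2.758
G039	10.373	10.373	10.373	9.186	9.186	8.748	8.984	8.653	8.387	9.183
G040	6.312	6.312	6.312	7.290	7.290	7.363	6.771	6.272	6.089	8.688
G041	6.078	6.078	6.078	5.066	5.066	4.703	4.841	4.458	5.008	6.669
G042	5.755	5.755	5.755	5.380	5.380	4.858	7.000	3.735	6.533	4.110
G043	3.130	3.130	3.130	3.480	3.480	2.430	1.190	2.470	2.899	2.013
G044	10.525	10.525	10.525	9.614	9.614	8.799	9.456	9.282	8.077	11.015
G045	6.031	6.031	6.031	4.427	4.427	6.291	5.733	6.670	4.894	5.423
G046	8.827	8.827	8.827	9.970	9.970	9.273	10.964	10.298	9.654	10.939
G047	9.030	9.030	9.030	8.821	8.821	9.253	9.173	7.939	7.935	8.835
G048	7.619	7.619	7.619	6.703	6.703	7.161	8.111	7.199	7.676	7.604
G049	9.005	9.005	9.005	8.913	8.913	9.768	8.452	9.293	7.799	9.947
G050	6.517	6.517	6.517	7.294	7.294	8.399	8.108	7.662	7.066	9.534
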