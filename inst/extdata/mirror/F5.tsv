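gene	F5_S01	F5_S02	F5_S03	F5_S04	F5_S05	F5_S06
G001	10.280	9.571	10.290	9.359	10.827	10.069
G002	10.379	8.667	8.786	8.827	10.146	9.061
G003	4.240	3.685	4.463	3.421	5.424	4.400
G004	8.936	8.251	8.119	8.207	8.995	9.801
G005	8.488	7.252	6.263	6.793	6.112	6.868
G006	7.330	8.038	7.026	5.184	5.464	5.514
G007	7.111	7.156	7.438	8.371	9.403	7.454
G008	4.236	1.352	4.374	4.216	3.640	2.236
G009	7.187	7.160	6.706	6.901	6.722	7.458
G010	6.382	6.970	8.167	6.809	7.076	7.903
G011	6.696	3.924	6.551	4.643	4.925	6.347
G012	7.821	7.054	9.466	8.369	7.872	9.194
G013	10.251	9.178	8.812	9.502	9.277	10.601
G014	5.594	3.161	4.104	2.519	3.290	3.042
G015	6.562	6.271	6.447	5.599	6.669	7.297
G016	9.237	10.246	9.119	9.520	9.535	9.631
G017	9.718	9.566	10.302	9.151	10.432	9.517
G018	2.150	1.755	2.595	1.963	2.636	4.425
G019	5.143	6.275	4.893	5.438	5.940	6.143
G020	6.875	5.799	4.693	5.921	7.310	7.868
G021	8.993	8.568	9.644	8.692	9.773	9.197
G022	3.637	3.229	2.836	1.268	3.863	2.525
G023	10.577	9.130	11.285	9.792	8.450	8.338
G024	9.864	9.337	8.680	10.332	9.715	10.474
G025	2.341	2.043	2.269	3.585	2.507	1.950
G026	4.916	6.428	6.760	7.773	5.594	6.811
G027	5.214	4.445	4.913	5.334	4.673	5.218
G028	8.416	8.571	9.636	8.404	10.587	9.624
G029	6.093	4.806	6.658	5.978	5.920	6.589
G030	9.306	8.697	10.429	9.568	8.572	8.300
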