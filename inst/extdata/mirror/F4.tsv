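gene	F4_S01	F4_S02	F4_S03	F4_S04	F4_S05	F4_S06	F4_S07	F4_S08
G001	9.226	9.330	9.519	7.946	7.631	8.556	10.865	9.312
G002	9.008	8.217	9.793	9.093	9.681	9.903	10.167	8.843
G003	5.166	4.510	4.615	4.045	5.498	4.304	4.141	4.249
G004	7.742	8.688	9.038	9.721	9.088	7.509	9.071	8.708
G005	7.904	6.950	7.178	6.928	7.866	7.613	8.562	5.886
G006	7.278	6.142	5.586	5.734	5.710	6.782	6.305	6.016
G007	6.580	8.201	7.846	7.362	8.132	7.785	7.438	7.558
G008	2.175	3.354	2.306	3.435	3.962	3.064	4.239	3.470
G009	7.729	6.911	7.331	7.000	6.193	8.383	8.751	6.831
G010	6.876	8.561	7.363	7.206	8.442	7.957	6.853	8.027
G011	5.109	5.633	5.567	5.438	4.535	6.638	6.237	6.091
G012	7.397	7.644	6.874	8.605	7.354	7.717	7.856	7.530
G013	9.201	10.233	9.251	10.731	11.575	10.661	10.038	9.442
G014	4.606	4.837	3.171	3.529	4.452	3.982	4.464	5.948
G015	5.216	5.137	5.373	5.714	5.625	6.432	5.682	6.936
G016	9.591	8.727	9.942	9.261	10.303	9.244	9.871	10.764
G017	10.416	9.262	10.018	11.312	9.631	8.964	8.858	9.872
G018	1.708	1.999	3.659	3.413	3.437	3.741	1.816	2.268
G019	5.248	4.375	6.190	4.375	5.524	7.637	6.377	6.257
G020	7.171	6.731	6.573	6.136	4.599	6.222	6.552	6.536
G021	8.931	9.116	10.031	7.398	9.610	10.407	9.127	12.100
G022	1.082	3.624	4.063	3.036	2.701	2.920	1.769	1.564
G023	9.225	9.910	8.791	10.474	9.452	10.650	9.455	9.749
G024	10.226	9.900	10.287	8.857	9.576	8.782	9.727	10.760
G025	2.319	2.263	3.282	1.634	3.734	2.881	2.271	0.981
G026	5.790	5.346	6.868	7.119	6.350	5.503	6.179	5.906
G027	5.005	5.745	4.395	4.350	5.795	4.040	5.430	5.389
G028	9.822	9.855	11.173	9.972	9.749	9.770	9.136	9.070
G029	5.183	4.189	3.501	5.747	5.657	6.864	5.918	4.831
G030	9.069	9.390	8.693	9.393	9.225	8.057	8.494	8.590
G035	2.491	0.613	2.126	2.834	1.921	1.325	1.777	3.103
G036	7.848	8.626	8.543	9.575	7.664	7.805	8.460	7.584
G037	2.010	1.743	2.657	3.048	2.337	1.692	2.570	3.191
G038	3.230	3.559	3.760	3.897	1.839	4.194	4.318	4.392
G039	9.587	10.130	8.631	9.390	8.464	9.823	11.121	8.264
G040	5.687	5.890	8.022	6.130	6.846	7.248	6.107	5.693
G041	6.267	4.824	4.801	4.068	4.907	5.644	4.470	5.064
G042	6.563	7.529	5.975	5.005	5.150	5.111	6.001	5.715
G043	1.625	1.116	1.766	2.190	3.090	2.161	3.609	3.248
G044	9.252	9.287	8.940	8.998	8.932	10.334	10.769	9.758
G045	4.727	5.421	4.969	6.120	3.363	5.229	5.080	5.790
G046	9.552	9.821	8.816	9.025	10.285	8.892	9.118	10.692
G047	8.701	8.675	9.528	9.374	9.138	8.000	10.459	10.039
G048	7.210	6.907	5.878	7.816	7.033	9.278	8.354	7.781
G049	8.268	10.635	8.985	8.822	9.455	8.408	9.940	10.027
G050	7.078	6.806	6.973	7.769	5.601	6.974	8.312	7.256
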