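gene	F3_S01	F3_S02	F3_S03	F3_S04	F3_S05	F3_S06	F3_S07	F3_S08
G001	10.073	9.744	9.629	10.048	8.769	9.535	8.674	9.489
G002	8.740	10.073	8.821	9.372	9.041	9.856	9.402	9.517
G003	4.090	4.737	4.879	2.662	4.753	5.751	4.420	5.381
G004	7.581	8.630	7.780	7.604	7.925	7.754	8.969	8.877
G005	7.810	4.437	500.000	6.448	6.982	8.314	7.645	7.772
G006	6.431	6.762	6.384	6.494	6.038	6.690	4.946	6.186
G007	8.624	7.580	7.966	7.665	7.816	6.657	7.899	7.238
G008	3.564	3.885	3.287	2.586	3.222	2.855	3.496	3.309
G009	6.770	6.754	7.311	6.580	8.533	6.753	8.317	7.528
G010	7.785	6.333	7.218	7.764	7.280	6.895	7.550	6.987
G011	4.135	6.658	5.558	4.981	5.026	4.432	6.941	5.639
G012	8.155	7.898	9.049	7.435	8.387	7.358	7.528	9.354
G013	10.252	12.273	9.463	8.725	9.781	9.129	9.437	8.574
G014	3.342	4.775	2.988	2.932	4.232	3.784	4.171	5.221
G015	3.989	6.537	5.022	6.462	6.171	4.049	5.296	5.516
G016	8.302	10.131	8.639	8.466	8.390	9.873	10.093	10.706
G017	8.936	9.343	9.106	9.884	10.677	10.423	8.749	9.152
G018	3.933	2.644	1.931	2.485	3.303	3.572	2.935	2.887
G019	5.803	6.648	3.699	4.953	6.561	6.417	5.368	6.049
G020	5.493	7.327	7.018	6.690	6.004	6.643	6.045	6.393
G021	9.677	9.698	9.760	9.531	7.758	10.407	10.153	9.759
G022	1.363	2.321	2.910	4.122	2.722	2.409	3.952	2.977
G023	9.713	11.259	9.332	10.171	9.186	8.930	11.189	10.878
G024	10.463	8.480	8.923	9.462	11.351	9.843	9.362	9.709
G025	2.387	2.313	2.979	4.742	2.329	3.013	2.686	3.214
G026	7.158	7.974	6.295	5.594	5.941	5.517	4.873	5.166
G027	6.558	5.541	5.459	4.319	5.972	5.151	4.811	4.595
G028	8.312	10.023	9.250	8.818	9.742	9.505	10.657	10.118
G029	4.654	5.878	6.071	5.488	6.114	5.880	5.243	5.983
G030	7.956	7.891	9.033	9.168	10.795	9.389	7.755	8.579
G031	8.324	7.423	8.348	8.234	8.034	8.648	7.935	7.814
G032	9.156	8.620	8.885	8.403	10.012	6.545	9.485	9.092
G033	6.072	2.762	6.435	4.420	5.308	6.487	3.843	4.926
G034	8.521	6.803	6.637	8.383	6.314	7.846	7.278	7.541
G035	2.893	2.671	3.239	2.765	0.250	1.576	2.406	0.715
G036	9.415	8.424	8.396	8.083	9.183	7.771	10.245	10.082
G037	2.190	1.832	2.007	2.608	1.260	2.783	1.567	2.672
G038	2.950	4.357	3.726	4.021	3.695	3.923	4.877	4.327
G039	8.672	8.818	8.894	10.089	10.675	10.115	8.907	7.729
G040	7.220	7.397	4.851	7.014	7.172	6.846	6.069	6.877
G041	6.383	3.898	4.786	4.123	4.806	4.841	4.129	4.709
G042	6.851	4.504	5.519	6.128	3.946	7.279	5.309	4.385
G043	0.758	0.960	0.909	1.716	1.658	0.670	2.281	2.881
G044	9.121	9.856	10.228	10.210	9.328	10.101	9.530	10.775
G045	6.589	5.289	4.976	6.793	6.001	5.762	6.296	5.011
G046	8.810	10.814	10.819	8.526	10.048	10.012	9.813	9.478
G047	7.811	9.069	9.314	10.352	9.113	9.549	9.017	10.471
G048	7.600	8.203	6.489	8.203	7.264	6.899	6.638	5.800
G049	11.154	11.324	9.902	9.345	9.538	10.701	8.731	10.363
G050	8.499	6.558	7.157	6.750	6.975	4.988	5.384	6.700
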