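gene	F2_S01	F2_S02	F2_S03	F2_S04	F2_S05	F2_S06	F2_S07	F2_S08
G001	301.631	304.627	294.680	257.545	313.673	271.923	297.357	256.179
G002	255.953	329.966	274.525	254.866	300.843	289.206	263.927	265.234
G003	114.177	128.733	139.521	142.948	102.902	137.023	78.682	161.380
G004	268.206	257.384	268.152	229.733	242.594	234.017	261.570	282.393
G005	168.396	237.132	207.531	219.885	196.113	211.506	213.976	192.811
G006	141.284	185.876	195.762	184.657	187.988	179.110	184.276	162.988
G007	209.866	226.352	250.575	204.913	236.695	252.999	252.821	278.150
G008	83.960	50.615	86.773	120.623	101.141	62.712	91.994	138.127
G009	247.414	187.351	245.814	203.453	201.904	188.881	236.305	199.029
G010	222.649	238.981	262.655	258.029	220.198	247.611	180.972	197.975
G011	173.757	134.828	153.972	158.459	187.653	155.746	142.784	232.824
G012	231.039	257.753	213.933	218.789	230.199	216.743	240.961	238.101
G013	267.384	251.996	296.635	283.561	268.607	287.022	275.840	288.792
G014	153.983	116.644	99.371	112.697	144.598	113.600	143.965	123.117
G015	144.624	170.884	160.154	162.382	171.264	215.733	146.827	204.657
G016	280.118	285.292	304.870	264.536	263.603	291.829	302.974	280.999
G017	286.432	298.427	281.017	265.670	335.813	298.657	278.728	329.805
G018	100.971	102.564	41.925	102.919	60.166	110.546	61.487	82.904
G019	212.574	170.971	189.945	154.651	131.255	172.561	165.773	186.124
G020	206.822	188.525	156.029	161.455	140.415	195.660	195.685	169.686
G021	310.137	280.808	244.450	264.772	292.587	251.211	247.496	281.051
G022	111.614	82.893	20.870	74.078	80.512	38.269	74.964	122.116
G023	282.340	334.228	317.280	244.703	290.717	268.357	267.422	293.408
G024	289.147	235.104	293.216	280.208	294.141	289.929	311.593	317.969
G025	112.826	104.448	90.895	83.812	68.604	55.001	97.167	145.253
G026	145.950	177.456	203.695	190.493	144.827	199.951	158.639	206.026
G027	161.454	163.796	152.653	163.086	106.865	171.062	167.036	147.693
G028	273.617	301.084	250.846	253.360	269.203	282.597	271.246	279.695
G029	188.347	187.334	180.811	159.463	171.473	162.440	140.559	156.866
G030	278.644	244.787	291.921	236.440	205.973	227.863	270.749	312.928
G031	244.255	274.568	201.025	221.780	244.003	229.615	229.279	166.019
G032	290.467	215.689	240.072	225.604	264.775	243.770	275.764	256.581
G033	116.538	173.884	146.136	126.355	184.224	169.067	148.473	155.793
G034	246.287	212.152	193.478	239.547	228.383	255.837	252.943	229.553
G035	23.051	14.943	77.619	54.419	65.879	72.985	48.726	23.572
G036	273.995	215.110	245.510	253.678	274.400	232.811	265.159	265.079
G037	63.921	67.654	91.936	103.279	61.311	101.874	70.657	66.274
G038	133.044	163.195	111.114	108.429	107.917	134.078	116.529	140.037
G039	279.481	284.151	295.064	264.700	280.374	282.955	282.437	290.154
G040	169.171	233.959	244.286	224.755	224.680	153.864	206.508	233.591
G041	102.892	171.208	157.455	139.386	140.729	128.170	148.899	128.100
G042	177.563	148.869	190.421	197.530	152.591	162.934	197.341	161.594
G043	67.209	91.865	74.027	59.906	48.206	87.241	90.765	73.572
G044	279.936	302.111	257.360	278.852	270.654	265.322	279.003	300.173
G045	156.154	168.578	164.158	135.585	171.463	240.689	197.134	146.968
G046	273.716	313.857	307.065	297.717	326.967	228.538	293.305	325.330
G047	269.284	290.999	284.807	308.256	249.807	267.398	257.685	258.378
G048	191.249	198.562	209.427	205.056	209.077	207.370	217.675	174.857
G049	245.448	302.525	263.815	299.315	268.320	277.119	289.268	302.700
G050	203.260	187.118	224.044	216.530	230.324	200.874	210.953	224.479
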