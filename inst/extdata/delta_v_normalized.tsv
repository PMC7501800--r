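# delta_V conservativeness matrix: 1 - |dvol|/max|dvol|, normalized to [0,1]
# built from Grantham (1974) side-chain volumes in property_scales.tsv
	A	R	N	D	C	Q	E	G	H	I	L	K	M	F	P	S	T	W	Y	V
A	1.000000	0.443114	0.850299	0.862275	0.856287	0.676647	0.688623	0.832335	0.610778	0.520958	0.520958	0.473054	0.556886	0.395210	0.991018	0.994012	0.820359	0.167665	0.371257	0.682635
R	0.443114	1.000000	0.592814	0.580838	0.586826	0.766467	0.754491	0.275449	0.832335	0.922156	0.922156	0.970060	0.886228	0.952096	0.452096	0.449102	0.622754	0.724551	0.928144	0.760479
N	0.850299	0.592814	1.000000	0.988024	0.994012	0.826347	0.838323	0.682635	0.760479	0.670659	0.670659	0.622754	0.706587	0.544910	0.859281	0.856287	0.970060	0.317365	0.520958	0.832335
D	0.862275	0.580838	0.988024	1.000000	0.994012	0.814371	0.826347	0.694611	0.748503	0.658683	0.658683	0.610778	0.694611	0.532934	0.871257	0.868263	0.958084	0.305389	0.508982	0.820359
C	0.856287	0.586826	0.994012	0.994012	1.000000	0.820359	0.832335	0.688623	0.754491	0.664671	0.664671	0.616766	0.700599	0.538922	0.865269	0.862275	0.964072	0.311377	0.514970	0.826347
Q	0.676647	0.766467	0.826347	0.814371	0.820359	1.000000	0.988024	0.508982	0.934132	0.844311	0.844311	0.796407	0.880240	0.718563	0.685629	0.682635	0.856287	0.491018	0.694611	0.994012
E	0.688623	0.754491	0.838323	0.826347	0.832335	0.988024	1.000000	0.520958	0.922156	0.832335	0.832335	0.784431	0.868263	0.706587	0.697605	0.694611	0.868263	0.479042	0.682635	0.994012
G	0.832335	0.275449	0.682635	0.694611	0.688623	0.508982	0.520958	1.000000	0.443114	0.353293	0.353293	0.305389	0.389222	0.227545	0.823353	0.826347	0.652695	0.000000	0.203593	0.514970
H	0.610778	0.832335	0.760479	0.748503	0.754491	0.934132	0.922156	0.443114	1.000000	0.910180	0.910180	0.862275	0.946108	0.784431	0.619760	0.616766	0.790419	0.556886	0.760479	0.928144
I	0.520958	0.922156	0.670659	0.658683	0.664671	0.844311	0.832335	0.353293	0.910180	1.000000	1.000000	0.952096	0.964072	0.874251	0.529940	0.526946	0.700599	0.646707	0.850299	0.838323
L	0.520958	0.922156	0.670659	0.658683	0.664671	0.844311	0.832335	0.353293	0.910180	1.000000	1.000000	0.952096	0.964072	0.874251	0.529940	0.526946	0.700599	0.646707	0.850299	0.838323
K	0.473054	0.970060	0.622754	0.610778	0.616766	0.796407	0.784431	0.305389	0.862275	0.952096	0.952096	1.000000	0.916168	0.922156	0.482036	0.479042	0.652695	0.694611	0.898204	0.790419
M	0.556886	0.886228	0.706587	0.694611	0.700599	0.880240	0.868263	0.389222	0.946108	0.964072	0.964072	0.916168	1.000000	0.838323	0.565868	0.562874	0.736527	0.610778	0.814371	0.874251
F	0.395210	0.952096	0.544910	0.532934	0.538922	0.718563	0.706587	0.227545	0.784431	0.874251	0.874251	0.922156	0.838323	1.000000	0.404192	0.401198	0.574850	0.772455	0.976048	0.712575
P	0.991018	0.452096	0.859281	0.871257	0.865269	0.685629	0.697605	0.823353	0.619760	0.529940	0.529940	0.482036	0.565868	0.404192	1.000000	0.997006	0.829341	0.176647	0.380240	0.691617
S	0.994012	0.449102	0.856287	0.868263	0.862275	0.682635	0.694611	0.826347	0.616766	0.526946	0.526946	0.479042	0.562874	0.401198	0.997006	1.000000	0.826347	0.173653	0.377246	0.688623
T	0.820359	0.622754	0.970060	0.958084	0.964072	0.856287	0.868263	0.652695	0.790419	0.700599	0.700599	0.652695	0.736527	0.574850	0.829341	0.826347	1.000000	0.347305	0.550898	0.862275
W	0.167665	0.724551	0.317365	0.305389	0.311377	0.491018	0.479042	0.000000	0.556886	0.646707	0.646707	0.694611	0.610778	0.772455	0.176647	0.173653	0.347305	1.000000	0.796407	0.485030
Y	0.371257	0.928144	0.520958	0.508982	0.514970	0.694611	0.682635	0.203593	0.760479	0.850299	0.850299	0.898204	0.814371	0.976048	0.380240	0.377246	0.550898	0.796407	1.000000	0.688623
V	0.682635	0.760479	0.832335	0.820359	0.826347	0.994012	0.994012	0.514970	0.928144	0.838323	0.838323	0.790419	0.874251	0.712575	0.691617	0.688623	0.862275	0.485030	0.688623	1.000000
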