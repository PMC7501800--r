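# SYNTHETIC exchangeability stand-in matrix (not the published EX matrix).
# Deterministic construction: complement of the mean normalized pairwise
# distance in side-chain volume, polarity (Grantham 1974) and hydropathy
# (Kyte-Doolittle 1982), min-max rescaled to [0,1].
# Conservative-change cutoff used downstream (after integer rescaling): score > 2
	A	R	N	D	C	Q	E	G	H	I	L	K	M	F	P	S	T	W	Y	V
A	1.000000	0.291809	0.466212	0.392864	0.752651	0.448953	0.353089	0.761432	0.439748	0.481542	0.500118	0.290825	0.657791	0.510331	0.818023	0.803627	0.763289	0.331712	0.449311	0.609863
R	0.291809	1.000000	0.701756	0.617487	0.175515	0.842856	0.736070	0.377480	0.852061	0.210200	0.228776	0.910918	0.353686	0.309977	0.462527	0.488182	0.528520	0.404935	0.563063	0.191084
N	0.466212	0.701756	1.000000	0.915731	0.349917	0.858900	0.886878	0.551883	0.808039	0.084269	0.102845	0.790838	0.260518	0.113058	0.636930	0.662585	0.675619	0.208016	0.366144	0.212590
D	0.392864	0.617487	0.915731	1.000000	0.271109	0.774632	0.881417	0.478535	0.723771	0.000000	0.018576	0.706570	0.176250	0.028790	0.563582	0.589237	0.591351	0.123747	0.281875	0.128321
C	0.752651	0.175515	0.349917	0.271109	1.000000	0.332659	0.236795	0.514083	0.323454	0.728891	0.747467	0.174531	0.821829	0.757680	0.590124	0.561739	0.646995	0.508134	0.546924	0.812179
Q	0.448953	0.842856	0.858900	0.774632	0.332659	1.000000	0.893215	0.534624	0.949139	0.225368	0.243944	0.841871	0.401618	0.254158	0.619672	0.645326	0.685664	0.349115	0.507244	0.348229
E	0.353089	0.736070	0.886878	0.881417	0.236795	0.893215	1.000000	0.438760	0.842353	0.118583	0.137159	0.825153	0.294833	0.147373	0.523808	0.549462	0.589800	0.242330	0.400458	0.246904
G	0.761432	0.377480	0.551883	0.478535	0.514083	0.534624	0.438760	1.000000	0.525419	0.242974	0.261550	0.376496	0.419223	0.271763	0.802370	0.889298	0.803927	0.316058	0.433657	0.371295
H	0.439748	0.852061	0.808039	0.723771	0.323454	0.949139	0.842353	0.525419	1.000000	0.276229	0.294806	0.851077	0.452479	0.305019	0.610466	0.636121	0.676459	0.399976	0.558105	0.339023
I	0.481542	0.210200	0.084269	0.000000	0.728891	0.225368	0.118583	0.242974	0.276229	1.000000	0.947649	0.209216	0.823750	0.856538	0.319014	0.290629	0.408649	0.554077	0.581609	0.871679
L	0.500118	0.228776	0.102845	0.018576	0.747467	0.243944	0.137159	0.261550	0.294806	0.947649	1.000000	0.227792	0.842326	0.875114	0.337591	0.309206	0.427226	0.572653	0.600185	0.849725
K	0.290825	0.910918	0.790838	0.706570	0.174531	0.841871	0.825153	0.376496	0.851077	0.209216	0.227792	1.000000	0.352702	0.281690	0.461543	0.487198	0.527536	0.376647	0.534776	0.190100
M	0.657791	0.353686	0.260518	0.176250	0.821829	0.401618	0.294833	0.419223	0.452479	0.823750	0.842326	0.352702	1.000000	0.852540	0.495264	0.466879	0.584899	0.663788	0.725095	0.814882
F	0.510331	0.309977	0.113058	0.028790	0.757680	0.254158	0.147373	0.271763	0.305019	0.856538	0.875114	0.281690	0.852540	1.000000	0.347804	0.319419	0.437439	0.697539	0.725072	0.758614
P	0.818023	0.462527	0.636930	0.563582	0.590124	0.619672	0.523808	0.802370	0.610466	0.319014	0.337591	0.461543	0.495264	0.347804	1.000000	0.890555	0.842815	0.442761	0.600890	0.447335
S	0.803627	0.488182	0.662585	0.589237	0.561739	0.645326	0.549462	0.889298	0.636121	0.290629	0.309206	0.487198	0.466879	0.319419	0.890555	1.000000	0.881980	0.404244	0.521842	0.418950
T	0.763289	0.528520	0.675619	0.591351	0.646995	0.685664	0.589800	0.803927	0.676459	0.408649	0.427226	0.527536	0.584899	0.437439	0.842815	0.881980	1.000000	0.512131	0.629730	0.536970
W	0.331712	0.404935	0.208016	0.123747	0.508134	0.349115	0.242330	0.316058	0.399976	0.554077	0.572653	0.376647	0.663788	0.697539	0.442761	0.404244	0.512131	1.000000	0.841871	0.478670
Y	0.449311	0.563063	0.366144	0.281875	0.546924	0.507244	0.400458	0.433657	0.558105	0.581609	0.600185	0.534776	0.725095	0.725072	0.600890	0.521842	0.629730	0.841871	1.000000	0.562494
V	0.609863	0.191084	0.212590	0.128321	0.812179	0.348229	0.246904	0.371295	0.339023	0.871679	0.849725	0.190100	0.814882	0.758614	0.447335	0.418950	0.536970	0.478670	0.562494	1.000000
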