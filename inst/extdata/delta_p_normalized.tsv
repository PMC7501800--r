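# delta_P conservativeness matrix: 1 - |dpol|/max|dpol|, normalized to [0,1]
# built from Grantham (1974) side-chain polarities in property_scales.tsv
	A	R	N	D	C	Q	E	G	H	I	L	K	M	F	P	S	T	W	Y	V
A	1.000000	0.703704	0.567901	0.395062	0.679012	0.703704	0.481481	0.888889	0.716049	0.641975	0.604938	0.604938	0.703704	0.641975	0.987654	0.864198	0.938272	0.666667	0.765432	0.728395
R	0.703704	1.000000	0.864198	0.691358	0.382716	1.000000	0.777778	0.814815	0.987654	0.345679	0.308642	0.901235	0.407407	0.345679	0.691358	0.839506	0.765432	0.370370	0.469136	0.432099
N	0.567901	0.864198	1.000000	0.827160	0.246914	0.864198	0.913580	0.679012	0.851852	0.209877	0.172840	0.962963	0.271605	0.209877	0.555556	0.703704	0.629630	0.234568	0.333333	0.296296
D	0.395062	0.691358	0.827160	1.000000	0.074074	0.691358	0.913580	0.506173	0.679012	0.037037	0.000000	0.790123	0.098765	0.037037	0.382716	0.530864	0.456790	0.061728	0.160494	0.123457
C	0.679012	0.382716	0.246914	0.074074	1.000000	0.382716	0.160494	0.567901	0.395062	0.962963	0.925926	0.283951	0.975309	0.962963	0.691358	0.543210	0.617284	0.987654	0.913580	0.950617
Q	0.703704	1.000000	0.864198	0.691358	0.382716	1.000000	0.777778	0.814815	0.987654	0.345679	0.308642	0.901235	0.407407	0.345679	0.691358	0.839506	0.765432	0.370370	0.469136	0.432099
E	0.481481	0.777778	0.913580	0.913580	0.160494	0.777778	1.000000	0.592593	0.765432	0.123457	0.086420	0.876543	0.185185	0.123457	0.469136	0.617284	0.543210	0.148148	0.246914	0.209877
G	0.888889	0.814815	0.679012	0.506173	0.567901	0.814815	0.592593	1.000000	0.827160	0.530864	0.493827	0.716049	0.592593	0.530864	0.876543	0.975309	0.950617	0.555556	0.654321	0.617284
H	0.716049	0.987654	0.851852	0.679012	0.395062	0.987654	0.765432	0.827160	1.000000	0.358025	0.320988	0.888889	0.419753	0.358025	0.703704	0.851852	0.777778	0.382716	0.481481	0.444444
I	0.641975	0.345679	0.209877	0.037037	0.962963	0.345679	0.123457	0.530864	0.358025	1.000000	0.962963	0.246914	0.938272	1.000000	0.654321	0.506173	0.580247	0.975309	0.876543	0.913580
L	0.604938	0.308642	0.172840	0.000000	0.925926	0.308642	0.086420	0.493827	0.320988	0.962963	1.000000	0.209877	0.901235	0.962963	0.617284	0.469136	0.543210	0.938272	0.839506	0.876543
K	0.604938	0.901235	0.962963	0.790123	0.283951	0.901235	0.876543	0.716049	0.888889	0.246914	0.209877	1.000000	0.308642	0.246914	0.592593	0.740741	0.666667	0.271605	0.370370	0.333333
M	0.703704	0.407407	0.271605	0.098765	0.975309	0.407407	0.185185	0.592593	0.419753	0.938272	0.901235	0.308642	1.000000	0.938272	0.716049	0.567901	0.641975	0.962963	0.938272	0.975309
F	0.641975	0.345679	0.209877	0.037037	0.962963	0.345679	0.123457	0.530864	0.358025	1.000000	0.962963	0.246914	0.938272	1.000000	0.654321	0.506173	0.580247	0.975309	0.876543	0.913580
P	0.987654	0.691358	0.555556	0.382716	0.691358	0.691358	0.469136	0.876543	0.703704	0.654321	0.617284	0.592593	0.716049	0.654321	1.000000	0.851852	0.925926	0.679012	0.777778	0.740741
S	0.864198	0.839506	0.703704	0.530864	0.543210	0.839506	0.617284	0.975309	0.851852	0.506173	0.469136	0.740741	0.567901	0.506173	0.851852	1.000000	0.925926	0.530864	0.629630	0.592593
T	0.938272	0.765432	0.629630	0.456790	0.617284	0.765432	0.543210	0.950617	0.777778	0.580247	0.543210	0.666667	0.641975	0.580247	0.925926	0.925926	1.000000	0.604938	0.703704	0.666667
W	0.666667	0.370370	0.234568	0.061728	0.987654	0.370370	0.148148	0.555556	0.382716	0.975309	0.938272	0.271605	0.962963	0.975309	0.679012	0.530864	0.604938	1.000000	0.901235	0.938272
Y	0.765432	0.469136	0.333333	0.160494	0.913580	0.469136	0.246914	0.654321	0.481481	0.876543	0.839506	0.370370	0.938272	0.876543	0.777778	0.629630	0.703704	0.901235	1.000000	0.962963
V	0.728395	0.432099	0.296296	0.123457	0.950617	0.432099	0.209877	0.617284	0.444444	0.913580	0.876543	0.333333	0.975309	0.913580	0.740741	0.592593	0.666667	0.938272	0.962963	1.000000
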