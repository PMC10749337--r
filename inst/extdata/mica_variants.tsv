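rsid	position	kind	ref	alts	freqs	ancestral	introduced
rs9266825	1122	substitution	C	A	C=0.6571;A=0.3429	C	new
rs1882	1151	substitution	A	G	A=0.2768;G=0.7232	A	new
rs9266826	1210	substitution	G	A	G=0.6571;A=0.3429	G	legacy
rs9266827	1216	substitution	A	G	A=0.6571;G=0.2429	A	legacy
rs9266828	1220	substitution	G	C	G=0.6571;A=0.3429	G	legacy
rs9266829	1242	substitution	A	G	A=0.6418;G=0.3582	A	legacy
rs140390705	1265	substitution	C	T	C=0.9994;T=0.0006	C	legacy
rs1880	1272	substitution	C	A	C=0.7736;A=0.2764	C	legacy
rs113015830	1311	substitution	T	A	T=0.9956;A=0.0044	T	legacy
rs1131904	1349	substitution	A	G	A=0.6573;G=0.3427	A	legacy
rs9266831	1361	substitution	G	A	G=0.6571;A=0.3429	G	legacy
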