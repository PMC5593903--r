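signature	ref_position	residues	role
conserved	112	R	required
conserved	116	P	required
conserved	167	W	required
conserved	170	A	required
conserved	258	G	required
conserved	287	P	required
conserved	307	D	required
conserved	518	A	required
conserved	557	G	required
conserved	563	G	required
conserved	778	L	required
conserved	779	P	required
conserved	785	E	required
set1	304	P	required
set1	774	A	required
set1	775	D	required
set1	778	L	required
set1	779	P	required
set1	785	E	required
set2	287	P	required
set2	307	D	required
set2	557	G	required
set2	563	G	required
set3	112	R	required
set3	116	P	required
set4	202	I	required
set4	266	T	required
set5	260	N	required
set5	535	G	required
set6	560	G	required
set6	565	G	required
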