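ref_pos	kind	ref_allele	alt_allele	copy
2709	substitution	G	A	unique
4878	substitution	T	C	duplication
4905	substitution	C	T	duplication
4908	substitution	G	A	duplication
5003	substitution	G	A	duplication
5036	substitution	G	A	duplication
5578	substitution	G	A	duplication
5687	substitution	G	A	duplication
5817	substitution	A	G	duplication
6333	substitution	C	A	duplication
6354	substitution	A	T	duplication
6732	substitution	C	T	primary
7016	insertion	-	AAAACC	primary
7018	substitution	A	C	primary
7050	insertion	-	G	primary
7452	substitution	C	T	primary
7624	substitution	T	G	primary
7699	deletion	AG	-	primary
8052	substitution	C	T	primary
8070	substitution	G	A	primary
8104	substitution	G	T	primary
8164	substitution	C	T	primary
8189	substitution	G	A	primary
8351	substitution	G	A	primary
9624	substitution	T	A	unique
13360	substitution	A	G	unique
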