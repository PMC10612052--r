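gene	ref_start	ref_end	new_start	new_end	copy
P	1726	2871	1798	2943	primary
M	3088	4014	3160	4086	primary
G	4140	5972	4212	6044	primary
X	6161	6490	6233	6562	primary
L1	6833	7074	6905	7153	primary
L2	7211	7740	7290	7817	primary
X1	6161	6490	9997	10326	duplication
L	6833	13255	10669	17091	duplication
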