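name	seq	ref_start	ref_end	orientation
F7	TCACATCTAGAGCTTGAAGACC	6209	6230	+
R7	TCTGCTCTTGACCACCAGGA	7304	7323	-
F9	CCATCTCCTTAGGTTTCCCAGA	8157	8178	+
R6	CACTGGCTGTGATGGTAGGT	6313	6332	-
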