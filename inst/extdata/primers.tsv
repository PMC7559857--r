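name	forward	reverse	max_amplicon
BatCV	ATCCAGCCGTAGAAGTCGTC	CGGAAAATCAAAGCGTGCAC	200
CyCV	TGAAGGAGGAGAGACATGCC	TGTTCCAGTCGATCCCCAAA	200
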