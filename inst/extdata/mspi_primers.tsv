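probe_id	forward	reverse
cg10695549	GCTGTAATTATACATCCAGCTATGG	TTTTTGTTTCCCTTCTGAGC
cg21028319	TTGCAAACGATGAGAACTGAG	CGTTTACCAGCCCATGCTA
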