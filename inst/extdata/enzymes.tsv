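name	recognition	cut_offset
MseI	TTAA	1
PstI	CTGCAG	5
AvaII	GGWCC	1
RsaI	GTAC	2
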