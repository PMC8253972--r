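node_id	network	lobe	hemisphere
a	MF	PFC	L
b	MF	PFC	R
c	DMN	Par	L
d	DMN	Par	R
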