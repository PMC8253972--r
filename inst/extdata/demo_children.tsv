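subject_id	a-b	a-c	b-c	a-d	b-d	c-d
c1	0.31	-0.12	0.55	0.08	-0.41	0.22
c2	-0.05	0.44	-0.27	0.63	0.11	-0.38
c3	0.52	0.09	-0.14	-0.33	0.47	0.05
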