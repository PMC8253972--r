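subject_id	a-b	a-c	b-c	a-d	b-d	c-d
p1	0.28	-0.09	0.49	0.12	-0.35	0.18
p2	-0.11	0.39	-0.22	0.58	0.16	-0.42
p3	0.47	0.14	-0.08	-0.29	0.52	0.01
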