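child_id	sex	timepoint	mean_fd	testosterone	cbcl
c1	M	age11	0.12	3.6	8.5
c2	F	age11	0.09	5.1	12.0
c3	F	age11	0.21		6.5
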