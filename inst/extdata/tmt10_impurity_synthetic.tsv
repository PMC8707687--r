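channel	minus2	minus1	plus1	plus2
126	0	0	6.1	0.2
127N	0	0.2	5.6	0.1
127C	0	0.5	4.8	0.2
128N	0	0.7	4.2	0.3
128C	0.1	1.1	3.6	0.1
129N	0.1	1.4	3.2	0.1
129C	0.2	1.7	2.8	0
130N	0.2	2.0	2.4	0
130C	0.3	2.5	1.8	0
131	0.3	3.0	1.6	0
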