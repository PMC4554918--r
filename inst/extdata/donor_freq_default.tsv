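position	A	C	G	T
1	0.35	0.40	0.15	0.10
2	0.70	0.10	0.10	0.10
3	0.10	0.05	0.80	0.05
4	0	0	1	0
5	0	0	0	1
6	0.70	0.05	0.15	0.10
7	0.75	0.05	0.10	0.10
8	0.10	0.05	0.80	0.05
9	0.15	0.15	0.15	0.55
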