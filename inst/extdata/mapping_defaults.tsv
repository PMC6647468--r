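item_id	fr2	fr3
1	0.3	0.3
2	0.3	0.3
6	0.3	0.3
7	0.3	0.3
8	0.3	0.3
12	0.3	0.3
15	0.3	0.3
18	0.3	0.3
22	0.3	0.3
23	0.3	0.3
24	0.3	0.3
25	0.3	0.3
26	0.3	0.3
28	0.3	0.3
29	0.3	0.3
30	0.3	0.3
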