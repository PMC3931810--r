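offset	A	C	G	T
-14	11	31	15	43
-13	10	32	12	46
-12	10	31	11	48
-11	9	33	10	48
-10	9	32	10	49
-9	9	33	9	49
-8	9	35	8	48
-7	8	37	8	47
-6	7	38	7	48
-5	6	39	6	49
-4	23	30	21	26
-3	3	64	2	31
-2	100	0	0	0
-1	0	0	100	0
1	24	15	49	12
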