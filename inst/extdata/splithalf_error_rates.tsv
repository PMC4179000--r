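participant	valence_a	valence_b	arousal_a	arousal_b
1	42	44	33	30
2	46	41	38	39
3	28	25	46	50
4	31	35	40	41
5	36	31	42	43
6	42	47	42	38
7	41	36	43	46
8	43	39	43	47
9	37	39	34	39
10	40	44	50	48
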