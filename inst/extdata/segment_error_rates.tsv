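participant	valence_first	valence_second	arousal_first	arousal_second
1	44.20	46.50	36.02	28.88
2	55.30	53.50	35.50	35.70
3	28.88	28.27	45.61	49.39
4	42.40	38.10	37.50	38.90
5	39.90	41.00	40.60	44.30
6	33.37	41.02	42.65	41.02
7	40.10	32.24	51.02	47.35
8	42.80	42.20	43.67	46.53
9	40.70	39.20	35.40	41.40
10	39.00	43.40	54.80	50.61
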