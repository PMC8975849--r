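nodes	edges	density	transitivity	clustering	pc2	pc3
2000	23213	0.0116	0.048	0.175	5e-4	0.0158
4000	46783	0.0058	0.028	0.158	2.5e-4	0.0111
6000	69307	0.0039	0.016	0.172	1.66e-4	0.0091
8000	91275	0.0028	0.010	0.187	1.25e-4	0.0079
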