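network	nodes	edges	density	transitivity	clustering	pc2	pc3
SWOW-EN free association	12217	352403	0.0047	0.052	0.113	8.2e-5	0.0064
Florida free association	5019	55246	0.0044	0.083	0.186	2.0e-4	0.0100
Edinburgh free association	8210	241461	0.0072	0.048	0.103	1.2e-4	0.0078
Taxonomic	7943	42042	0.0013	0.048	0.093	1.3e-4	0.0079
Synonyms	6526	13134	0.0006	0.284	0.344	1.5e-4	0.0088
Phonological	4618	15447	0.0014	0.345	0.246	2.2e-4	0.0104
Multiplex	8383	68505	0.0019	0.112	0.283	1.2e-4	0.0078
RUS thesaurus	5377	51191	0.002	0.067	0.163	1.9e-4	0.0096
Dutch data	10486	207810	0.0038	0.067	0.163	9.5e-5	0.0069
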