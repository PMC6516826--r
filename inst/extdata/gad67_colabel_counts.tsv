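animal	slice	plane	n_tdtomato	n_gad67	n_colabeled
P58_female_1	1	caudal	210	184	3
P58_female_1	2	middle	172	65	2
P58_male	1	caudal	151	152	2
P58_male	2	middle	46	212	2
P58_female_2	1	caudal	161	137	0
P58_female_2	2	middle	53	187	1
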