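haplogroup	parent	snp_id	position	ancestral	derived
H001	ROOT	s00001	13609	C	G
H001	ROOT	s00002	74742	C	A
H002	ROOT	s00003	102661	C	G
H002	ROOT	s00004	106092	T	A
H003	ROOT	s00005	142295	A	G
H003	ROOT	s00006	185657	A	T
H004	ROOT	s00007	238549	A	C
H004	ROOT	s00008	248033	G	A
H005	H001	s00009	249761	T	G
H005	H001	s00010	250882	A	G
H006	H003	s00011	321502	C	G
H006	H003	s00012	326553	A	T
H007	H001	s00013	340097	A	C
H007	H001	s00014	343444	T	A
H008	H001	s00015	391481	T	C
H008	H001	s00016	426928	A	T
H009	ROOT	s00017	498845	G	C
H009	ROOT	s00018	507825	G	A
H010	H007	s00019	521507	A	C
H010	H007	s00020	586328	T	A
H011	H006	s00021	626545	A	C
H011	H006	s00022	683918	T	A
H012	H003	s00023	689059	T	C
H012	H003	s00024	743620	C	T
H013	H008	s00025	765799	A	C
H013	H008	s00026	841220	T	C
H014	H004	s00027	859667	C	A
H014	H004	s00028	926594	C	T
ROOT	.	.	.	.	.
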