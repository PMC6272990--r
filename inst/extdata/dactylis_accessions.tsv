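code	accession	subspecies	country	range	climate
1	PI237605	santai	Algeria	Unknown	Mediterranean
2	PI368880	santai	Algeria	Unknown	Mediterranean
3	PI441034	smithii	United Kingdom	Africa	Subtropical
4	PI237607	smithii	Spain	Africa	Subtropical
5	PI538922	woronowii	Russian Federation	Asia-Temperate	Mediterranean
6	PI237610	woronowii	Iran	Asia-Temperate	Mediterranean
7	PI237602	lusitanica	Portugal	Europe	Mediterranean
8	PI295271	himalayensis	India	Asia-Tropical	Temperate
9	PI538920	glomerata	Russian Federation	Unknown	Temperate
10	PI316209	lobata	Bulgaria	Europe	Temperate
11	PI372621	lobata	Germany	Europe	Temperate
12	PI283242	lobata	Germany	Europe	Temperate
13	PI231517	hispanica	Morocco	Africa	Mediterranean
14	PI265568	hispanica	Spain	Europe	Mediterranean
15	PI265567	hispanica	France	Europe	Mediterranean
16	PI224599	hispanica	Israel	Unknown	Mediterranean
17	PI277836	hispanica	Turkey	Asia-Temperate	Mediterranean
18	PI231550	hispanica	Greece	Europe	Mediterranean
19	PI231541	hispanica	Portugal	Europe	Mediterranean
20	PI577065	marina	Portugal	Europe	Mediterranean
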