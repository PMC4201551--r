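no	position	contig_source_1	contig_source_2	mapping_ambiguity	hp_base	hp_class	hp_run_length
1	57036	TT	TT	TRUE	T	AT	2
2	65465	TTCCTATTTAATA	TTCCTATTTAATA	TRUE	T	AT	1
3	66897	TAGAAATAAAAAATTCTAA	TAGAAATAAAAAATTCTAA	TRUE	C	GC	1
4	66902	TAGAAATAAAAAATTCTAA	TAGAAATAAAAAATTCTAA	TRUE	C	GC	1
5	17366	T	T	TRUE	T	AT	2
6	17368	-	-	FALSE	C	GC	2
7	3545	AA	AAA	FALSE	A	AT	10
8	21808	C	C	FALSE	C	GC	3
9	57027	T	T	FALSE	T	AT	3
10	81342	G	G	FALSE	G	GC	3
11	91427	C	C	FALSE	C	GC	3
12	91589	C	C	FALSE	C	GC	3
13	97135	G	G	FALSE	G	GC	2
14	111639	G	G	FALSE	G	GC	3
15	116139	C	C	FALSE	C	GC	4
16	118025	C	C	FALSE	C	GC	3
17	119245	G	G	FALSE	G	GC	2
18	122914	C	C	FALSE	C	GC	3
19	123568	G	G	FALSE	G	GC	4
20	133816	C	C	FALSE	C	GC	3
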