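no	type	position	ref_allele	allele_a	allele_b	most_probable
1	MNV	57036	TT	TT	AA	TT
2	ins	65465	-	-	TCCTATTTAATA	TTCCTATTTAATA
3	MNV	66897	CGAT	TAGA	CGAT	TAGAAATAAAAAATTCTAA
4	SNP	66902	C	A	C	TAGAAATAAAAAATTCTAA
5	SNP	17366	T	A	T	T
6	SNP/del	17368	C	A	-	-
7	ins	3545	-	AA	A	-
8	del	21808	C	C	-	C
9	del	57027	T	T	-	T
10	del	81342	G	G	-	G
11	del	91427	C	C	-	C
12	del	91589	C	C	-	C
13	del	97135	G	G	-	G
14	del	111639	G	G	-	G
15	del	116139	C	C	-	C
16	del	118025	C	C	-	C
17	del	119245	G	G	-	G
18	del	122914	C	C	-	C
19	del	123568	G	G	-	G
20	del	133816	C	C	-	C
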