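name	total_count	n_isomirs	most_expressed_sequence	length_nt	counts	seed
Novel-2	1553	31	UUACCACAGGGAUAACUG	18	232	UACCACA
Novel-16	270	4	AUCAUUUUUGUGACUAUGCAACU	23	264	UCAUUUU
Novel-7	668	9	UGAGAACUGAAUUCCAAGGGUGU	23	332	GAGAACU
Novel-127	3127	28	AGGUGUUGGUUGAUAUAGACA	21	389	GGUGUUG
Novel-117	744	3	CUGACGUGCAAAUCGGUC	18	484	UGACGUG
Novel-118	5064	63	UGCGGACCAGGGGAAUCC	18	484	GCGGACC
Novel-115	3368	25	CGAAUGACUAGAGGCCUUGG	20	526	GAAUGAC
Novel-40b	1879	4	UUGACUCUAGUCUGGCAC	18	1096	UGACUCU
Novel-59	13127	78	CUGGCACUGUGAAGAGACAUGAGG	24	1204	UGGCACU
Novel-51	9024	51	UGCGGGAUGAACCGAACGCC	21	1234	GCGGGAU
Novel-50	1738	4	AACGGGCUUGGCAGAAUC	18	1272	ACGGGCU
Novel-33	3867	15	GAUUAUGACUGAACGCCU	18	1540	AUUAUGA
Novel-15b	8773	80	AUGGCGCUGGAGCGUCGGGCCC	22	1693	UGGCGCU
Novel-15a	16536	59	GAUGGCGCUGGAGCGUCGGGCCC	23	2001	AUGGCGC
Novel-13	7224	19	CAGGAUAGCUGGCGCUCGCC	20	2087	AGGAUAG
Novel-40a	117202	112	UUGACUCUAGUCUGGCACUGUGAAGA	26	6095	UGACUCU
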