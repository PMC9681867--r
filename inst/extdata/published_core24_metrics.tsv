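marker	chrom	pos	alleles	maf	pic	variant_type	f10
QN01-1	C1	16912365	T/A	0.38	0.36	Missense	FALSE
QN19-7	C1	30133135	A/T	0.41	0.37	Missense	TRUE
QN32-10	C1	40348257	A/C	0.30	0.33	Synonymous	FALSE
QN12-2	C1	42832899	T/A	0.27	0.32	Missense	FALSE
QN20-9	C2	2493581	T/G	0.33	0.34	Synonymous	FALSE
QN22-15	C2	21153749	A/T	0.37	0.36	Missense	FALSE
QN02-11	C2	41871386	G/T	0.24	0.30	Missense	TRUE
PQ25-11	C2	47959189	A/C	0.43	0.37	Missense	FALSE
PQ18-17	C2	51429603	C/A	0.09	0.15	Synonymous	FALSE
PQ18-18	C3	1728366	A/G	0.28	0.32	Missense	TRUE
QL24-5	C3	1728375	T/C	0.28	0.32	Missense	FALSE
PQ17-13	C3	16381523	G/C	0.41	0.37	Synonymous	FALSE
QN02-23	C3	21935944	T/G	0.42	0.37	Missense	FALSE
PQ11-18	C3	34450549	C/G	0.33	0.34	Missense	FALSE
PQ11-20	C3	58838243	T/C	0.33	0.35	Synonymous	TRUE
PQ6-30	C5	6622086	G/C	0.40	0.36	Synonymous	TRUE
QN22-50	C5	42891943	G/C	0.36	0.35	Missense	TRUE
QN15-28	C5	46259901	T/A	0.36	0.36	Missense	FALSE
QN01-49	C6	4834902	A/C	0.21	0.28	Synonymous	TRUE
QL16-30	C6	37280236	T/A	0.41	0.37	Synonymous	TRUE
PQ25-55	C7	20974235	T/C	0.11	0.18	Up/downstream_gene	FALSE
QN04-34	C7	32444765	T/C	0.26	0.31	Synonymous	TRUE
QN12-40	C7	43517964	G/A	0.27	0.31	Synonymous	FALSE
PQ17-44	C9	4150485	G/A	0.33	0.34	Synonymous	TRUE
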