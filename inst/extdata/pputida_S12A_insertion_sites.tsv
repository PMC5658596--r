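replicon	variant	position	orientation	presence_in_previous	dr_seq	dr_len	context
Chromosome	ISS12	5798528-2596	Reverse	No	GGAAGTG	7	Integrase - Peptidase S24 [b]
Chromosome	ISS12	1303416-1306017	Forward	No	TCTGTG	6	Membrane protein (UPF0114 family) - cation transporter [b]
Chromosome	ISS12_C	1343201-1345781	Forward	No	CACTACC	7	Putative Holin - putative integrase [b]
Chromosome	ISS12	1508754-1511356	Forward	No	CGCCGAC	7	Major facilitator transporter (MFS) [a]
Chromosome	ISS12	1901500-1904102	Forward	No	TTCTTCG	7	ABC transporter [a]
Chromosome	ISS12	2092282-2094884	Forward	Yes	GCAAAAC	7	Copper resistance gene [a]
Chromosome	ISS12	2509647-2512248	Forward	No	CAACAT	6	Hypothetical protein [a]
Chromosome	ISS12	2747110-2749712	Forward	No	GCATAGC	7	Amidohydrolase, SalR regulator [a]
Chromosome	ISS12	2756345-2758947	Reverse	No	GACGGTT	7	Benzoylformate decarboxylase [a]
Chromosome	ISS12	2767364-2769967	Reverse	No	CTCGTATG	8	Serine - tRNA ligase [c]
Chromosome	ISS12	2913093-2915695	Reverse	No	CCATGAC	7	Hypothetical (First gene in Type IV secretion operon) [a]
Chromosome	ISS12	3486765-3489368	Forward	No	CACAGGGA	8	PrrB RsmZ-like ncRNA [a]
Chromosome	ISS12	3503916-3506518	Reverse	No	CGAGGTG	7	TRNA 2-thiocytidine biosynthesis protein [c]
Chromosome	ISS12	4425759-4428360	Forward	No	CGGGGG	6	Glutaminase [a]
Chromosome	ISS12	4894007-4896609	Reverse	Yes	CGCAAGT	7	Glycosyl hydrolase family 32 [a]
Chromosome	ISS12	4905864-4908466	Forward	No	AGCTCGA	7	Hypothetical protein [a]
Chromosome	ISS12_D	4954933-4957427	Forward	Yes	ATGACA	6	Hypothetical [c]
Chromosome	ISS12	4963941-4966543	Forward	Yes	GACAAGC	7	SH3 domain-containing protein [a]
Chromosome	ISS12	5273052-5275654	Reverse	No	CATAGGC	7	GntR transcriptional regulator - Transporter [a]
Chromosome	ISS12_C	5324675-5327253	Forward	No	GGCAGTC	7	Transposase [c]
Chromosome	ISS12	5641776-5644378	Forward	Yes	CTTGATG	7	Major facilitator transporter (MFS) [a]
Plasmid	ISS12_C	53788-56369	Reverse	Yes	GCCCTGCC	8	Transposase - Hypothetical protein [b]
Plasmid	ISS12	80378-82980	Forward	No	TCTACAC	7	Tellurium resistance-like protein [a]
Plasmid	ISS12	115546-118148	Forward	No	CGTAGGG	7	Hypothetical protein [a]
Plasmid	ISS12	200772-203372	Forward	Yes	CCTTGCC	7	Hypothetical protein [a]
Plasmid	ISS12	218063-219257	Forward	No	CCGCT	5	Hypothetical protein [a]
Plasmid	ISS12	240098-242700	Forward	Yes	ACCAACC	7	Hypothetical protein [a]
Plasmid	ISS12_C	245315-247895	Reverse	Yes	GATAGAT	7	Carbon storage regulator [a]
Plasmid	ISS12	286656-289258	Reverse	Yes	ACCCGCT	7	Hypothetical protein [a]
Plasmid	ISS12	312315-313509	Forward	No	ACCCAGA	7	Solvent resistance pump (SrpA) [a]
Plasmid	ISS12	399104-401706	Forward	No	GCCAACG	7	Hypothetical protein [a]
Plasmid	ISS12	463678-466280	Reverse	No	CTCCTGG	7	Hypothetical protein [a]
Plasmid	ISS12	488389-490991	Forward	No	CGCATGGC	8	Hypothetical protein [a]
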