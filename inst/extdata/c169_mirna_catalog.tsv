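family	name	sequence	class
miR156	csl-miR156a	TGACAGAAGAGAGTGAGCAC	conserved
miR157	csl-miR157a-5p	TTGACAGAAGATAGAGAGCAC	conserved
miR159	csl-miR159a	TTTGGATTGAAGGGAGCTCTA	conserved
miR159	csl-miR159a-5p	AGCTCCCTTCGATCCAATC	conserved
miR159	csl-miR159a-3p	CTTGGATTGAAGGTAGCTCT	conserved
miR159	csl-miR159b	TTTGGATTGAAGGGAGCTCTATT	conserved
miR160	csl-miR160a-3p	GCGTATGAGGAGCGAAGCATA	conserved
miR162	csl-miR162a-3p	ATCGATAAACCTCTGCATCCAG	conserved
miR164	csl-miR164a	TGGAGAAGCAGGGCACGTGCA	conserved
miR164	csl-miR164a-1	TGTAGAAGCAGGGCACATGCC	conserved
miR166	csl-miR166a-3p	TCGGACCAGGCTTCATTCCCC	conserved
miR166	csl-miR166a-5p-1	GGAATGTTGTCTGGTTCAAGG	conserved
miR166	csl-miR166a-5p	GGAATGTTGTCTGGCTCGGGG	conserved
miR166	csl-MIR166b-3p	GATAATGATAATGATAATG	conserved
miR166	csl-MIR166b-5p	TAATGATAATGATAATGATAAT	conserved
miR166	csl-miR166e-3p	TGGAACCAGGCTTCATTCCCC	conserved
miR166	csl-miR166h-5p	GGAATGTTGGCTGGCTCGAGG	conserved
miR166	csl-miR166i-3p	TCTCGGATCAGGCTTCATTCC	conserved
miR166	csl-miR166j	CCGGACAAGGCTTCATTCCCC	conserved
miR166	csl-miR166k-5p	GGTTTGTTGTCTGGCTCGAGG	conserved
miR166	csl-miR166m	GCTGACCAGGCTTCATTCCCC	conserved
miR167	csl-miR167e	TGAAGCTGCCAGCATGATCTT	conserved
miR168	csl-miR168	TCTCTTGGTGCAGGTCGGGAA	conserved
miR168	csl-miR168a-3p-1	CCCGCCTTGCATCAACTGAAT	conserved
miR168	csl-miR168a-3p	CCCGCCTTGCACCAAGTGAAT	conserved
miR168	csl-miR168a-5p	TCGCTTGGTGCAGGTCGGGAA	conserved
miR171	csl-miR171a	TTGAGCCGCGTCAATATCTCC	conserved
miR171	csl-miR171h	TGAGCCGAACCAATATCACTC	conserved
miR171	csl-miR171k-3p	TTGAGCCGCGCCAATATCACT	conserved
miR172	csl-miR172a	AGAATCTTGATGATGCTGCAT	conserved
miR319	csl-miR319	GTGGGACTGAAGGGAGCTCCC	conserved
miR319	csl-MIR319a-5p	TAACACGTCCGGGTTGCT	conserved
miR319	csl-miR319a-3p	TTGGACTGAAGGGTGCTCCCT	conserved
miR319	csl-miR319a-5p	AGAGCTTCCTTCAGTCCACTCA	conserved
miR319	csl-miR319b	GCTTGGACTGAAGGGAGCTCCTTC	conserved
miR319	csl-miR319b-5p	AGAGCGTCCTTCAGTCCACTC	conserved
miR390	csl-miR390-3p	CGCTATCTATCCTGAGCTCC	conserved
miR390	csl-miR390-5p	AAGCTCAGGAGGGATAGCGCC	conserved
miR393	csl-miR393a	TCCAAAGGGATCGCATTGATT	conserved
miR394	csl-miR394a-5p	TTGGCATTCTGTCCACCTCC	conserved
miR396	csl-miR396a-3p-1	GTTCAATAAAGTTGTGGGAAG	conserved
miR396	csl-miR396a-3p	CTCAAGAAAGCTGTGGGAGA	conserved
miR396	csl-MIR396a-5p	TTGATGATCTTCTTCAAAA	conserved
miR396	csl-miR396a-5p-1	TTCCACAGCTTTCTTGAACTG	conserved
miR396	csl-miR396a-5p	TCCACAGGCTTTCTTGAACTG	conserved
miR396	csl-miR396b	TTCCACAGCTTTCTTGAACTTTT	conserved
miR397	csl-miR397a	TCATTGAGTGCAGCGTTGATG	conserved
miR397	csl-miR397b-5p	TTGAGTGCAGCGTTGATGAACC	conserved
miR398	csl-miR398c	CATGTGTTCTCAGGTCGCCCC	conserved
miR403	csl-miR403-3p	TTAGATTCACGCACAAACTCG	conserved
miR408	csl-miR408-3p	TGCACTGCCTCTTCCCTGGCT	conserved
miR414	csl-MIR414-5p	ACATCATCATCGTCATCATC	conserved
miR444	csl-miR444c	TGCAGTTGTTGTCTCAAGCTT	conserved
miR477	csl-miR477a	ACTCTCCCTCAAGGGCTTCTGA	conserved
miR482	csl-miR482-3p	TTCCCAATTCCGCCCATTCCTA	conserved
miR482	csl-miR482-5p	GGAATGGGCTGATTGGGAAGC	conserved
miR482	csl-miR482a-3p	TTCCCAAGCCCGCCCATTCCAA	conserved
miR482	csl-miR482a-5p	GGAATGGGCTGTTTGGGATG	conserved
miR482	csl-miR482b-3p	TCTTCCCTACACCTCCCATACC	conserved
miR482	csl-miR482c	TCTTTCCTACTCCACCCATTCC	conserved
miR528	csl-miR528-5p	TGGAAGGGGCATGCAGAGGAG	conserved
miR529	csl-miR529-5p	AGAAGAGAGAGAGTACAGCCT	conserved
miR535	csl-miR535-5p	TGACAACGAGAGAGAGCACGC	conserved
miR812	csl-miR812a	GACGGACGGTCAAACGTTGGACAC	conserved
miR827	csl-miR827	TTAGATGACCATCAGCAAACA	conserved
miR894	csl-miR894	CGTTTCACGTCGGGTTCACCA	conserved
miR946	csl-miR946	CAGCCCTTCTCCTATCCACAAT	conserved
miR1314	csl-miR1314	CCGGCCTCGAATGTTAGGAGAA	conserved
miR1423	csl-miR1423-5p	GCAACTACACGTTGGGCGCTCGAT	conserved
miR1425	csl-miR1425-5p	TAGGATTCAATCCTTGCTGCT	conserved
miR1448	csl-miR1448	TCTTTCCAACGCCTCCCATACC	conserved
miR1507	csl-miR1507a	TCTCATTCCATACATCGTCTGA	conserved
miR1509	csl-miR1509a	TTAATCAAGGAAATCACGGTCG	conserved
miR1510	csl-miR1510b-3p	TGTTGTTTTACCTATTCCACCT	conserved
miR1510	csl-miR1510b-5p	AGGGATAGGTAAAACAACTAC	conserved
miR1511	csl-miR1511	AACCCGGCTCTGATACCA	conserved
miR1850	csl-miR1850.1	TGGAAAGTTGGGAGATTGGGG	conserved
miR1862	csl-miR1862e	CTAGATTTGTTTATTTTGGGACGG	conserved
miR1876	csl-miR1876	ATAAGTGGGTTTGTGGGCTGGCCC	conserved
miR2109	csl-miR2109-3p	GGAGGCGTAGATACTCACACC	conserved
miR2118	csl-miR2118a-3p	TTGCCGATTCCACCCATTCCTA	conserved
miR2118	csl-miR2118b	TTCCCAATGCCTCCCATTCCTA	conserved
miR2118	csl-miR2118f	TCCTGATGCCTCCCATTCCTA	conserved
miR2118	csl-miR2118o	CTCCTGATGCCTCCCAAGCCTA	conserved
miR2275	csl-miR2275b-3p	TTCAGTTTCCTCTAATATCTCG	conserved
miR2275	csl-miR2275b-5p	AGGATTAGAGGGAACTGAACC	conserved
miR2275	csl-miR2275c	AGAATTGGAGGAAAACAAACT	conserved
miR3522	csl-miR3522	TGAGACCAAATGAGCAGCTGA	conserved
miR3624	csl-miR3624-3p	TCAGGGCAGCAGCATACTA	conserved
miR3630	csl-miR3630-3p	TGGGAATCTCTCTGACGCT	conserved
miR4412	csl-miR4412-5p	TGTTGCGGGTATCTTTGCCTC	conserved
miR4413	csl-miR4413a	TAAGAGAATTGTAAGTCACTG	conserved
miR4995	csl-miR4995	GGCAGTGGCTTGGTTAAGGGAACC	conserved
miR4996	csl-miR4996	TAGAAGCTCCCCATGTTCTCA	conserved
miR5054	csl-miR5054	TCCCCACGGACGGCGCCA	conserved
miR5072	csl-miR5072	TTCCCCAGTGGAGTCGCCA	conserved
miR5077	csl-miR5077	GTTCACGTCGGGTTCACCA	conserved
miR5139	csl-miR5139	CGAAACCTGGCTCTGATACCA	conserved
miR5368	csl-MIR5368-3p	CTGGGATTGGCTTTGGGC	conserved
miR5372	csl-miR5372	TTGTTCGATAAAACTGTTGTG	conserved
miR5527	csl-miR5527	TCTCAGCCAGGGCAGTAACAG	conserved
miR5530	csl-miR5530	AGTGGTGTCGTATTACCTGCC	conserved
miR5724	csl-miR5724	AACCGCCGGTTCGATAAT	conserved
miR5770	csl-miR5770a	TTAGGACTATGGTTTGGACGA	conserved
miR5792	csl-miR5792	GATGACAGCGGTGGTTCGGACCTC	conserved
miR5796	csl-miR5796	TCATTCAGGATTGAAGCCGCC	conserved
miR5818	csl-miR5818	TCGAACTAGAAGGGCCAGGTT	conserved
miR6300	csl-miR6300	GTCGTTGTAGTATAGTGGT	conserved
miR6478	csl-miR6478-2	CCGACCTTAGCTCAGTTGGTAGA	conserved
miR6478	csl-miR6478-1	CCGGCCTTAGCTCAGTTGG	conserved
miR6478	csl-miR6478	CCGACTTTAGCTCAGTTGG	conserved
miR7700	csl-MIR7700-5p	TCAGTGGTGGTGGTGGTGG	conserved
miR8005	csl-MIR8005c-3p	TTTAGGGTTTAGGGTTTAGG	conserved
miR7972	csl-miR7972	TTGTCAGGCTTGTTATTCTCC	conserved
miR8155	csl-miR8155-1	GTAACCTGGCTCTGATACCA	conserved
miR8155	csl-miR8155	AACCTCGCTCTGATACCA	conserved
miR8175	csl-miR8175	TCGTTCCCCGGCAACGGCGCCA	conserved
miR9558	csl-MiR9558-5p	CACTGTGGCAAAGATATG	conserved
csl-nmiR1	csl-nmiR1	AGGGCGTTCCGTCGGACGGGTT	novel
csl-nmiR2	csl-nmiR2	GCCAAAGTGACTGCAGGCT	novel
csl-nmiR3	csl-nmiR3	TCTCTGCATTGGGCTGGATCT	novel
csl-nmiR4	csl-nmiR4	GCCATGACAAGAATGCTGGGCC	novel
csl-nmiR5	csl-nmiR5	GCCTACAGTCACTTTGGCT	novel
csl-nmiR6	csl-nmiR6	TGCAGAGATGGGACGGCT	novel
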