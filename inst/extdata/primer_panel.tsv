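set_name	main_target	level	gene	orientation	sequence	ecoli_position	size_bp	tagged	parent_set
bacteria_A	Bacteria	domain	16S	forward	AGAGTTTGATCCTGGCTCAG	7	NA	TRUE	NA
bacteria_A	Bacteria	domain	16S	reverse	CTGCTGCCTYCCGTA	342	336	TRUE	NA
bacteria_B	Bacteria	domain	16S	forward	CAGCAGCCGCGGTAATAC	518	NA	TRUE	NA
bacteria_B	Bacteria	domain	16S	reverse	CCGTCAATTCCTTTGAGTTT	906	389	TRUE	NA
firmicutes	Firmicutes	phylum	16S	forward	CTGATGGAGCAACGCCGCGT	385	NA	TRUE	NA
firmicutes	Firmicutes	phylum	16S	reverse	ACACYTAGYACTCATCGTTT	813	429	TRUE	NA
bacilli	Bacilli	class	16S	forward	GCAGTAGGGAATCTTCCGC	353	NA	TRUE	firmicutes
bacilli	Bacilli	class	16S	reverse	ACACTTAGCACTCATCGTTT	813	461	TRUE	firmicutes
enterococcus	Enterococcus	genus	16S	forward	GGGTAACCTRCCCATCAGA	125	NA	TRUE	bacilli
enterococcus	Enterococcus	genus	16S	reverse	GTTACTCTCATCCTTGTTC	449	325	TRUE	bacilli
enterococcus	Enterococcus	genus	16S	reverse	ACCGTCAGGGGACGTTCAG	466	342	TRUE	bacilli
lactobacillus	Lactobacillus	genus	23S	forward	GCGGTGAAATTCCAAACG	774	NA	TRUE	bacilli
lactobacillus	Lactobacillus	genus	23S	reverse	GGGACCTTAACTGGTGAT	989	216	TRUE	bacilli
streptococcus	Streptococcus	genus	16S	forward	CTWACCAGAAAGGGACGGCT	488	NA	TRUE	bacilli
streptococcus	Streptococcus	genus	16S	reverse	AAGGRYCYAACACCTAGC	824	337	TRUE	bacilli
clostridium_I	Clostridium cluster I	family	16S	forward	AAAGGAAGATTAATACCGCATA	159	NA	TRUE	firmicutes
clostridium_I	Clostridium cluster I	family	16S	reverse	TTCTTCCTAATCTCTACGCA	696	538	TRUE	firmicutes
c_perfringens	Clostridium perfringens	species	16S	forward	TGAAAGATGGCATCATCATTCAAC	183	NA	FALSE	clostridium_I
c_perfringens	Clostridium perfringens	species	16S	reverse	GGTACCGTCATTATCTTCCCCAAA	440	258	FALSE	clostridium_I
clostridium_IV	Clostridium cluster IV	family	16S	forward	ACAATAAGTAATCCACCTGG	866	NA	TRUE	firmicutes
clostridium_IV	Clostridium cluster IV	family	16S	reverse	CTTCCTCCGTTTTGTCAA	1163	298	TRUE	firmicutes
clostridium_XIV	Clostridium cluster XIV	family	16S	forward	CGGTACCTGACTAAGAAGC	482	NA	TRUE	firmicutes
clostridium_XIV	Clostridium cluster XIV	family	16S	reverse	CTTTGAGTTTCATTCTTGCGAA	894	413	TRUE	firmicutes
bacteroidetes	Bacteroidetes	phylum	16S	forward	CCGGAWTYATTGGGTTTAAAGGG	554	NA	TRUE	NA
bacteroidetes	Bacteroidetes	phylum	16S	reverse	GGTAAGGTTCCTCGCGTA	967	414	TRUE	NA
bacteroides	Bacteroides	genus	16S	forward	AAGGTCCCCCACATTGG	302	NA	TRUE	bacteroidetes
bacteroides	Bacteroides	genus	16S	reverse	GAGCCGCAAACTTTCACAA	601	300	TRUE	bacteroidetes
actinobacteria	Actinobacteria	phylum	16S	forward	GCGKCCTATCAGCTTGTT	235	NA	TRUE	NA
actinobacteria	Actinobacteria	phylum	16S	reverse	CCGCCTACGAGCYCTTTACGC	567	333	TRUE	NA
bifidobacteriaceae	Bifidobacteriaceae	family	16S	forward	CTCCTGGAAACGGGTGG	152	NA	TRUE	actinobacteria
bifidobacteriaceae	Bifidobacteriaceae	family	16S	reverse	CTTTCACACCRGACGCG	593	442	TRUE	actinobacteria
bg_proteobacteria	Beta-gamma-proteobacteria	class	23S	forward	GTATAATGGGTCAGCGAC	569	NA	TRUE	NA
bg_proteobacteria	Beta-gamma-proteobacteria	class	23S	reverse	CAGCATTCGCACTTCTGA	1241	673	TRUE	NA
enterobacteriaceae	Enterobacteriaceae	family	16S	forward	CGTCGCAAGMMCAAAGAG	182	NA	TRUE	bg_proteobacteria
enterobacteriaceae	Enterobacteriaceae	family	16S	reverse	TTACCGCGGCTGCTGGCAC	514	333	TRUE	bg_proteobacteria
e_coli	Escherichia coli	species	16S	forward	GTTAATACCTTTGCTCATTGA	461	NA	FALSE	enterobacteriaceae
e_coli	Escherichia coli	species	16S	reverse	ACCAGGGTATCTAATCCTGTT	780	320	FALSE	enterobacteriaceae
e_proteobacteria	Epsilon-proteobacteria	class	16S	forward	TGGTGTAGGGGTAAAATCCG	680	NA	TRUE	NA
e_proteobacteria	Epsilon-proteobacteria	class	16S	reverse	AGGTAAGGTTCTTCGYGTATC	965	286	TRUE	NA
d_proteobacteria	Delta-proteobacteria	class	16S	forward	GGTGTAGGAGTGAARTCCGT	681	NA	TRUE	NA
d_proteobacteria	Delta-proteobacteria	class	16S	reverse	TACGTGTGTAGCCCTRGRC	1214	534	TRUE	NA
fusobacteria	Fusobacteria	phylum	16S	forward	GATCCAGCAATTCTGTGTGC	387	NA	TRUE	NA
fusobacteria	Fusobacteria	phylum	16S	reverse	CGAATTTCACCTCTACACTTGT	678	292	TRUE	NA
verrucomicrobia	Verrucomicrobia	phylum	16S	forward	GAATTCTCGGTGTAGCA	673	NA	TRUE	NA
verrucomicrobia	Verrucomicrobia	phylum	16S	reverse	GGCATTGTAGTACGTGTGCA	1223	551	TRUE	NA
spirochaetes	Spirochaetes	phylum	16S	forward	GTYTTAAGCATGCAAGTC	45	NA	TRUE	NA
spirochaetes	Spirochaetes	phylum	16S	reverse	TGCTGCCTCCCGTAGGAG	338	294	TRUE	NA
archaea	Archaea	domain	16S	forward	CAGCMGCCGCGGTAATWC	518	NA	TRUE	NA
archaea	Archaea	domain	16S	reverse	YCCGGCGTTGAMTCCAATT	957	440	TRUE	NA
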