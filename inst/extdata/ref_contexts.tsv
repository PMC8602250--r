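contig	start	seq
ChrX	108591626	ACCTATCCCTGTCTCCCTCTC
Chr5	141524204	TGCAGATGTGCGACACGGGTT
Chr11	77192129	TGCGCGTTAAGGCACTGGCCC
Chr17	18142112	TAGTAGGTGCGTGTAATATCG
Chr17	18153848	TCTCTTTTTATAGACATACAA
Chr12	80255173	CATATTGAATCAAAGGCGCGG
Chr12	80320650	GAACTCGCCAAGACCATCAACCGCGGCGGCCATCATCGAATCTCCGGAGGCAATTAGCCTATTCATGACCACATTCAAAGACTGGCACAGACGTTGGTGCGTAGAG
Chr11	121127915	GTGCCTTTCTTACAGCTCCAA
Chr11	121166757	CTCATTGGTCGTTCCACAACG
Chr11	121168054	GAGATCGATTCTCAACCGTTA
Chr11	121168125	CCTATACACACGCGTGGCACA
Chr11	121168741	TTTAATGGAAACACAGTGATC
Chr11	121190770	TGTCGAGATCCCGTCGAGCGCCCAGTACAACCAATATTAC
Chr9	72821017	AGTGATAGGTCGGATCTCTGG
Chr21	42388925	AAACACGAAAGGATTAAACGT
Chr21	44499913	CCGAAGTGTACAAAGCATGCA
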