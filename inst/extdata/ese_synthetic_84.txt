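# synthetic ESE hexamer set (84 motifs): generated purine-rich
# stand-in for a consensus ESE catalogue; not a published motif list
GTAAAA
ATAGGA
AAGGAG
TGTAAG
AAAGTA
GTAAGA
ATAGAG
GGGAGA
CGAAGG
AGAGTA
AAGGAA
AAAGGG
TCGGGA
GCACTT
ATAAAA
GAGAAG
GAGAGA
CAAAGA
GGGGTA
ATCGGA
GAAAGC
GGGAAG
TGTAAC
AGAGCG
AAAAAG
AATGCG
CATAGA
GGACGG
GACAGT
AAGGCG
AAGAAT
GAGGGT
GGAGAG
AAGAGG
GTATAC
GGAAGG
AGAAAG
GAGGAA
CGAAGA
AGCGGG
AAGAGA
GTAGCA
AGAAAA
TGTCGA
AATAGC
GTAAAG
CTAAAG
AAAAAA
GTGAAG
GAAGAC
AACTTG
GATACG
CGAGAA
GAAACA
GAAGAG
CAAGAA
AAACAA
ATGCAA
TTAGAT
GGAAAA
AGACAG
AATGGA
ATGGAG
GAACTG
TTAAGA
AGTCAA
AAAAGA
CAAAAA
ACAAAG
GTAGAA
GTGAAA
GACGAG
GGAAGA
TCGACA
GATGAA
AAAGCA
ATTAAA
AGGAGT
AAAACA
CATAAT
AAGGGT
CGGTCT
AATATG
CGTAGG
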