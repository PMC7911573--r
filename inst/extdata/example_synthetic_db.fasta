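>SH010001.97 k__Fungi;p__Ascomycota;c__Eurotiomycetes;o__Eurotiales;f__Trichocomaceae;g__Aspergillus;s__Aspergillus_fumigatus
ACCAGAAGTCCCCATTTTGGTACGCTCGTCTTTGTGTCACCATCGATGAAGAACGCAGCAATTGAGGACGGGACCGGGTC
TTCTCGCTATCAACTCCACCCTCCCGATAGGCATACGAGAATTCCGGCTCTTTCTATACGAACCTCGGTAGTCATCGACG
AACCTGTGAGCAACCGGTTAAGGCTACCTTACCGATTTTCCTTGTTCTCAAGCAATCTCCCGAACAGCCTGCGTAGATTC
TCCAGGCCAAGGGGCTCGGTTGACTCAGTGAAACCTTCGACTGTAACTCTGAAACAACTCGCCTCGAACGACAGTCGAGC
AGCTCTGCGGAGCATATCAATAAGCGCAGGAATACAGCGCTCAAATCGGTCATTTAGAGGAAGTAATAGTCCTGGACATC
CCCCAATTATGTGGCATTCCATAAATAAACATGGTCCAAGATTGATAGGAAGAGTACTAGGTATTCATAGTGCTTCATGG
AATCAAGTGATAATAAACTGCAGAAGCACTCATCTACTAGGAAAATAATGACTTTAGCCACGCACAGTCCACCGTTTTAC
ATGACTCGGTAATTTTTTGGCTGCATCGATGAAGAACGCAGCGTCCCAGTCTACATCAGTACAGTCACATGGTCCTGGAC
GG
>SH010002.97 k__Fungi;p__Ascomycota;c__Eurotiomycetes;o__Eurotiales;f__Trichocomaceae;g__Aspergillus;s__Aspergillus_fumigatus
GGACCAGCTTGGGTAGAGGCACCTTTCCGTTAATAGAGGACATCGATGAAGCCGGCAGACCGGCTTCGGAGTTTAATTTA
CAAGTGGCCCGATCATCTAACCATCGCAAGGGCCCGGTCAACTTGTAGGATCAAATTCGCCCGACAGTGTTACGCGTGGT
ATCGATGTACACCGTTAGTATTCAATAGTGGCCAACCGTACAGCGTCGCTCTCGATGTCCGCCTAGTTATCGTTGCGGTG
TGAATCAGCAGGCCCTGCGATTAATTATAATACACCACTTCGGGTGGGGCTCTCCAAGTACTACAAGAGGTTTGCTTCGC
ATATCAATAAGCGGAGGAACCCGGTCTTGCACGGGGTCATTTAGAGTAAGTAACCCCGCATCGAAAAATTCTCGTGGCAC
CACGTTCCGTAACTAGTTCAGAGTAACGCGTGGTCTCGTGGCGACAAACAACACCTTAGACCTTGTCCGAATCTTGCTAT
GCTCATTCGGACATTAATCCCTGAACGCAATTCTATCGATGGTCACGTCAGGGCACAAACGCTGCTGGTTACACTATCGC
ATCGATGAAGAACGCAGCAGCTACGGGCCATAGTCAATCAGCTTGGCGTAAGTTCATG
>SH010003.97 k__Fungi;p__Ascomycota;c__Eurotiomycetes;o__Eurotiales;f__Trichocomaceae;g__Aspergillus;s__Aspergillus_fumigatus
GGGCACGGCGCTATGCACCCTTGACAGTGCAGCCGAGTGACATCGATGAAGAACTCAGGCATTTTTCCGACGGAAACTAC
CACTTAACGGAACCGAAAGTGAGAATTACACGGTCTAACGATTCATCGCGAGTGGGAATAAGCCTACTTTCTCAGTACGA
CGCCTCAAAATTAAATTTCTCAGCTTTTCCGGGTTCATACATCGACCGGTCTTGCTCTTCGCCTTAAGCGCGCCCGGACA
GCGCGCGGGAGGCCTGCGCCCCTCTGCAACGGGGTTACAATCGCCGAATCTCTTTTCATTGACTGACCGCCGTGGACATT
GACTTAAACTACGGGCATATCAATAAGCGCAGGAACGCCTAATACAAGAGGGTCAGTTGGAGGAAGTAACTGACCGGATA
AAGATATAAAATGGACAAAATACTGCACTAATCCCTCCTTCTTATTTGCGGTCGCGCCCGTCGGTCAGTAGTTAGATCAT
GGTGGCGAAATGTGGATTCGGAACATCGTCTGTCCGGCACGCGCGAACTGTGGTGCACGATGGTTCCAGAAGAAGTACCA
AAAAGCAGCATAGCATCGATGAAGAACGCAGCAGCCAATTGCACGCGTGGCCACAGGCTGTAAAAAGGCAGC
>SH010004.97 k__Fungi;p__Ascomycota;c__Eurotiomycetes;o__Eurotiales;f__Trichocomaceae;g__Aspergillus;s__Aspergillus_fumigatus
TTACTAAACCAGAGGGTAGAAAGTGAGTTGTGCCTATACACATCGATGAAGATCGAAGACTGGTAGAGACGGTTACGAGA
TACTCGAGATCAACGTATGAGGGCCACTCCCGTTCCTACTCGCATGGAGTGAGAGCATGAGTGTTCGACTCAGTGCTCGT
TTGAGACGACTTACACGGCGCGAAATAAGCTATGTGCAGGGAATCGCGGTTCGTACCGGCTCTGCTAAACTTCAGAATTA
TCGCAGCGATAATCCTGCTAGTGAGTCCCCGACACTTACCGTGCCTGAGCCCCGACAGGTTGCGCATATCAATAAGCGGA
GGAATCTGCGGTTCTTGTGATTCATTTAGAGGAATTAACCGCTTGAAATATGCGAGGGAATTACCACCCACGTGACGACA
TGTAGCTAGGTAGGGCACCCAAAATATGGTAGCGGCTGTATTTAACGGGGGGTGGTTACATGCAGCATTTGTCCGTTTTA
ACTACCTCTTCAAAAGTCAAGTTGCTCCCAAGGGAAGGCGCCAACGTAAAGCATCGATGAAGAACGCAGCAGAATTTCAG
AGCGAGCGAAAGAGAGTAGTTTCGCGGACC
>SH020001.97 k__Fungi;p__Basidiomycota;c__Agaricomycetes;o__Cantharellales;f__Tulasnellaceae;g__Tulasnella;s__Tulasnella_calospora
TCGAAACATGTGGGTTCTATCCAAAGGGCGGAAGGTGTTGCATCGATGAAGAACGCAATCTATATATCACTCTGTTGGCA
AAGTAGGGGGGCAGAGTACGAAAATGGAACTTAGTCTGTGCTAGCGTATCCGGTCTACGAATCTCTATGGTCGGGATTTC
CAACCGGCACGAAGGTTGACAGGCACCAACACGACGTATTAGGCAAGCTGCGTCAGAATCGCACTATGTCCTGAGTAGCT
TTTCTGTAGGATTTGAATAAACTAGGCTCTTTCGTTTTCTACAAGTCACGAAGATAACACCTGCGCTTTGTCGTCGGAAC
GAAAGAACGGGCTAGTGCGAGATTGCATATCAATAAGCGGAGGAAGGCATCGGATTATCCGGTCATTTAGAGGAAGTAAT
GCAACGCAAACACTAAGTGGTATCCATTGCAGACATTGCCATTCTTTGGGGGTACGATCAGGTTTATGATTCAATTAGTC
GTTTACATTCTTGGGAGCCTGAGGAATAACTCTAATCGTAGTGCCGCCGCATGCTCTATACTACGCATACAATACCCCGC
TCGTTGATCTACTTTATCTTGATCAGCATCGATGAAGAACGCAGCAGTGTGTGTACTCTTAGATTTCATGAAGTCGTGGA
GAATT
>SH020002.97 k__Fungi;p__Basidiomycota;c__Agaricomycetes;o__Cantharellales;f__Tulasnellaceae;g__Tulasnella;s__Tulasnella_calospora
AAGTTTATAGACAGACGGTACGGTCATTCTAAGTGATTATCATCGATGAAGAACGCACGTACTCATATTCACTCTGGAGT
GCCTCGCATACGCGGATTGCTAACCGGACCAGTAGTCTTCTTTTCTTAACTTACGCGAAAGAGGGCAATGAGACATGAGC
ATTGCGCTAACACGACGCAATAAATTCGTGGGACCTTGATACGGTAGTCCAGCTGTCCGCTGTCGACGGTCACAAACTGG
GCAAGAAATGTGATCCCACTCAACAACGAGTACGCAGCCCCAGGACATTTACCAAGGGGGCTGACAAATCTATAATAAGT
CTAAATGCATATCAATAAGCGGAGGAACTTTAACCTCCGCCTATAACGGACGTCAATACAGGATACATACAGAGCGAGCG
CAAACAGGATACTCTAAACAAGGCCCGGGGAAGTTTCCAACCAATCAACCCGAATAGACTATGCTAGACGGCGACGTGCG
CAAATCCATATACCGTGCGTCGTCGCTTTAGAATTCTGAAGGGTAGGTTGGAAAGTGGATTTGCATCGATGAAGAACGCA
GCGCCGCGGGCCCCAATCACGGCGGTGATGTGAAATGATTGA
>SH020003.97 k__Fungi;p__Basidiomycota;c__Agaricomycetes;o__Cantharellales;f__Tulasnellaceae;g__Tulasnella;s__Tulasnella_calospora
GCATATGTGGGGCGAAGCTCAACACAAGATTAGTGAAGGCCATCGATGAAGAACGCATACTATGGGGGATTGTGACTATA
CGAGCCCAGCATGCTAGCCGTTTGCCGGTGATTTATGCTCATTCGCGTCGGCAGAGGCCACCCGAAACCTATCGAAACTT
ACCGGCTAGTAAACACCGATTCCAGTCCCTGAGAAATACTCGATTCAATCTCTCATTACTTCTCGTTTCCCGACACGTGC
CAACTTTTGTGCAAATGCTGTGACTGGTTAGACCAGTAATCAGAAACTGTGACAGCATACAAACCGAAGTACCACCTTAC
AGCATATCAATAAGCGGAGGAAGATACGTCTCAGAACGGGAGCCTTTCAGGTGTCTCGAGGTACTACTTATAGCGCATGA
TGTAGGTGAGCCATGGCTTTCTCTACGCAGGTTGCTCTCCTCATGTCCGTTCGCGGTTTACCACCCGCTCTTTGTGGATT
CCTGGTATATGAAAATAGGCAACGAACGAGAGAGGGGCAGGTTTCTGTGAGTACAACAAACCGCTGCGCCCTCGCATCGA
TGAAGAACGCAGCCCTTGTGACGGTTGGCAGCTTTAACTTAACCAAAGCCTCG
>SH020004.97 k__Fungi;p__Basidiomycota;c__Agaricomycetes;o__Cantharellales;f__Tulasnellaceae;g__Tulasnella;s__Tulasnella_calospora
ACCGCCCCGAGAACCCGTATGAAATAGATTCGTCCCGTCGCATCGATGAAGAACGCTGAAGGGCCACAATGTGGTGGAGT
GAGTACAGATCGTACATCCTATCTTTTCAATGTCATGCTCTTCATCAATGATAATCTGGGCGAAAGCTAATTTGGGTCGC
CTAGCTGAATTATAGCGTCCGCTATGTCCCACCTAACTTAACTTAGCAATTCAGCGGAGGTTTAGCGCCTGCCGCGGCAA
TCGATCTGTCGTCTGCTAGCACGTAGCATAATTCCCACAAACATGTGTACGTGGATACTAGAACGTGCGCCCGTTGCGCC
CGATGATGCATATCAATAAGCGGAGGAAACCACCGAAAACACTGGTCATTTATAGGAAGTAAAACGGTAGGCTGGACGTT
TAGCGCCAAAGTCTGTGTCACACTCACTACAAGCACAGGACTATTGTTGCACTAGGTAGCCTTGCCTAAACTATACTGCT
TCTGCGCACCGGCGCGAGCAGTGCGTGTAAGCTCGCGACGCGAAAAGAAATACACTGTTATTGGTCATGAGGAATAGCTG
AAACTGCATCGATGAAGAACGCAGCTGGAGCGAGCCCTTTTGTGGCCCCGTCACACAGCGCTTCG
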