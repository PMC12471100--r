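>trna-Lys_synthetic synthetic tRNA stand-in; 3' terminus used for PBS matching
GCCCGGCTAGCTCAGTCGGTAGAGCATGGGACTTTTAATCCCAGGGTCGTGGGTTCGAGC
TGGCGCCCGAACAGGGAC
>trna-Leu_synthetic synthetic tRNA stand-in
ACCAGGATGGCCGAGTGGTTAAGGCGTTGGACTTAAGATCCAATGGACATATGTCCGCGT
GGGTTCGAACCCCACTCC
>trna-Gly_synthetic synthetic tRNA stand-in
GCATTGGTGGTTCAGTGGTAGAATTCTCGCCTGCCACGCGGGAGGCCCGGGTTCGATTCC
CGGCCAATGCACCAGGAC
>trna-Met_synthetic synthetic tRNA stand-in
AGCAGAGTGGCGCAGCGGAAGCGTGCTGGGCCCATAACCCAGAGGTCGATGGATCGAAAC
CATCCTCTGCTATGGAAC
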