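>demo_m01 label=homolog
UCUCGCACACCAUUGUCUACCGCCAAGUAGGCAGUCUGAUAUACAUCCGUCUCUCCUAUAUGGGGGAGAC
GCUAACAGAG
>demo_m02 label=homolog
ACUCUUCAACUAUUUUCCACGCCUUAGGAGACAGUAUGCUAUUAAUCCUUAUCGCCGCUAUUGGCGAUAG
GCGAACAAAC
>demo_m03 label=homolog
UCUUAUGAACCAUUGUCUAGCCGUAUUUAGACAGGCGGAUAUAGAUCCUGAUCUCCAAUAUUGGGGAUUG
GCUAAUAAAC
>demo_m04 label=homolog
UGUAGUGGCCCAUCGUGUACCUUUAAGUACACGAUACGAUAUUCUUUGGUAUCUUCAAUGUUGGGGAUAC
UCUAAUACAC
>demo_m05 label=homolog
UAUCAAUGACGAGUAGGUACCCUUAUGUACCUACUAGGAUUUUCAUCCGUACCUCCAGUACUGGGGGAAC
GCUAAUAAAA
>demo_m06 label=homolog
UCUCGUGAACCAUUAUCUAACGCUAAUUAGAUAGUAGGAGAUUCAUCCGUAUCUCCAACAUUGGGGAUAC
GCUAAUCAAC
>demo_m07 label=homolog
CCUCGUGAACCAUUGUCUAUCCCUUAGUAGACAGUUUGAUAUUCAUCCGUGUCUCCACCAUUGGGGACAG
GCGAAGAAAC
>demo_m08 label=homolog
UCUCGUGCACCUUUGUUUAUCGCCUAGUAAACGGUACGAUAAGCAUCCGUACCUCCAAUACUGGGGGUAC
GCAAGUAAAC
>demo_m09 label=homolog
UCGCGUGAAGCAUUCGCUACCACUGAGUAGUGGGUAGUAUAUUAAUCCGUAUUUCUAAUAUCGGGAAUAC
GCUAUCAAAC
>demo_m10_shuffled label=decoy
UCUAUUGCACUAUUGUCAUACGCAGGAGGGGCAGUACAUCGUUCGUACCGAUCUCCAACAUUGGGGGACC
UCGUAUAAAU
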