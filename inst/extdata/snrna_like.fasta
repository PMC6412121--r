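>U1 five_prime=monophosphate three_prime=linear-phosphate
AUACUUACCUGGCAGGGGAGAUACCAUGAUCACGAAGGUGGUUUUCCCAGGGCGAGGCUU
AUCCAUUGCACUCCGGAUGUGCUGACCCCUGCGAUUUCCCCAAAUGUGGGAAACUCGACU
GCAUAAUUUGUGGUAGUGGGGGACUGCGUUCGCGCUUUCCCCUG
>U2 five_prime=monophosphate three_prime=linear-phosphate
AUCGCUUCUCGGCCUUUUGGCUAAGAUCAAGUGUAGUAUCUGUUCUUAUCAGUUUAAUAU
CUGGUUCACGUGAGGUAACUCCCCGCGUCAUACAGUUUCCCACUACGAGGGGAAAAGCCC
CUGGUCGUGAGAGGCCUAGCAAUCGGGCGCUGGAACGCUCUUCUAACGUUUGGUGGUCCU
CCUUUUGA
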