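#structure ......(((((.....))))).....((((((....))))))....((((((((......))))))))....((((((((.......))))))))......
>t9
AUUAAUGCUUACGAUUUAAGCGGAAUGUUAAAACACUUUAACUUAUUCCGAUAAGUAGUUUUAUCGGACACGGGUUUACGUUACGCCCGUAAACCUCUAGA
>t6
AUUAAUGCUUACGAUUUAAGCGGAAUGCUAAAAGACUUUAGCUAAUUCCGAUAAUUACUUUUAUCGGACACGGGUUUACGUUGUGCCCGUAAACCUCUAGU
>t8
AUGAAUGCUUACGCUGUAAGCGGAAUGUUAAAAGUCUUUAACUAAUUCCGAUAAAUACUCUUAUCGGACCCGCGUUUACGUUGCUCCCGUAAACGUCUAGA
>t4
AUGAGUGCUUACCAUGUAAGCGGAAU----------------UAAUUCCGAUAAUUACCUUUAUCGG-UCCGUGGUUACGUUGGUCGCGUAACCAUCUAGA
>t1
AUUAAUGCUUAGCGUUUAAGCGGAGUGUUAAAAGAAUUUAACUAAUUCCGAUAAUUAAUUUUAUCGGACACGGAUUUACGUUGCGCCCGUAAAUCUCUAGA
>t3
AUUUAUGCUUAUGACUUAAGCAGAAUGUUAAAGAACUUUAACUAAUUCCGAUAACUACUUUUAUCGGAGACGGGUUGACGUUGCGCCCGUCAACCUCUAGA
>t10
AUUUAUGCUUAUGACUUAAGCGGAAAGUUAAAGAACUUUAACUAAGGCCGAUAACUACAUUUAUCGGACAUGGGUUUACGUUGCGCCCGUAAACCCCUAGA
>t2
GAAAAG---------------AAAAUGUUAAAAACCUUUAACAAGUCACGGCCACUACCUUGGCCGUGCAGCGGUUUACGUUGCACCCGUAAACCUCUAGA
>t7
~~~~~~~~~~~~~~~~~~~--UAAAUGUUCAAAACCUUGAACAAGUCCCGGCAACUACCUUUGCCGGGCAGGGGUUUACGUUGCACCCGUAAACCUCUAGA
>t5
GUAAAUGCUUAUGAUUUAAGCGGAAUGUUAAAAGCCUUUAACUAAUUCCGACAACUACUUUUGUCGGACAGGGGUUUACGUUGCACCCGUAAACCUCUAGA
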