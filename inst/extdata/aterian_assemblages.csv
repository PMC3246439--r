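assemblage,n,country,collection_class
Bir-Chaacha,51,Algeria,excavated
Bir-el-Ater,19,Algeria,excavated
Contrebandiers,33,Morocco,excavated
el-Mnasra,20,Algeria,excavated
el-Oubira,97,Algeria,excavated
Oued Djouf el Djemel,140,Algeria,excavated
Tit Mellil,35,Morocco,excavated
Beni-Abbes,23,Algeria,surface
Djouf Djoudder,10,Mali,surface
Erg Chech,9,Algeria,surface
Erg Jmeyha,4,Mali,surface
Koudiat Bou Gherara,2,Algeria,surface
Nord Azraza,3,Mali,surface
Polygone d'Eckmuhl,16,Algeria,surface
Oua-n-Torha,3,Algeria,surface
Oum-el-Ksi,4,Mali,surface
RDAC/REDA (Ouargla),20,Algeria,surface
Unknown North Africa,13,NA,surface
Tebessa,5,Algeria,surface
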