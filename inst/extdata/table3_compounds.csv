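flavonoid,pubchem_record,split
"5,7,2'-Trihydroxyflavone",Structure2D_CID_21611827,train
"Naringin",Structure2D_CID_442428,train
"(+/-)-Taxifolin",Structure2D_CID_471,train
"Quercetin",Structure2D_CID_5280343,train
"Apigenin",Structure2D_CID_5280443,train
"Luteolin",Structure2D_CID_5280445,train
"Rutin",Structure2D_CID_5280805,train
"Kaempferol",Structure2D_CID_5280863,train
"Genistein",Structure2D_CID_5280961,train
"Baicalein",Structure2D_CID_5281605,train
"Chrysin",Structure2D_CID_5281607,train
"Resokaempferol",Structure2D_CID_5281611,train
"Galangin",Structure2D_CID_5281616,train
"Isorhamnetin",Structure2D_CID_5281654,train
"Morin",Structure2D_CID_5281670,train
"Myricetin",Structure2D_CID_5281672,train
"Scutellarein",Structure2D_CID_5281697,train
"Tamarixetin",Structure2D_CID_5281699,train
"Daidzein",Structure2D_CID_5281708,train
"3-Methyl galangin",Structure2D_CID_5281946,train
"5-Hydroxyflavone",Structure2D_CID_68112,test
"3,6,4'-Trihydroxyflavone",Structure2D_CID_688684,test
"3,4'-Dihydroxyflavone",Structure2D_CID_688715,test
"(+/-)-Naringenin",Structure2D_CID_932,test
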