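flavonoid,observed,predicted,residual,split
"5,7,2'-Trihydroxyflavone",0.519,0.518,-0.001,train
"Naringin",0.519,0.468,-0.051,train
"(+/-)-Taxifolin",0.477,0.584,0.107,train
"Quercetin",0.792,0.590,-0.202,train
"Apigenin",0.462,0.490,0.028,train
"Luteolin",0.447,0.539,0.092,train
"Rutin",0.38,0.431,0.051,train
"Kaempferol",0.663,0.547,-0.116,train
"Genistein",0.580,0.490,-0.090,train
"Baicalein",0.462,0.499,0.037,train
"Chrysin",0.491,0.449,-0.042,train
"Resokaempferol",0.431,0.498,0.067,train
"Galangin",0.491,0.512,0.021,train
"Isorhamnetin",0.732,0.611,-0.121,train
"Morin",0.505,0.595,0.090,train
"Myricetin",0.556,0.630,0.074,train
"Scutellarein",0.431,0.534,0.103,train
"Tamarixetin",0.663,0.602,-0.061,train
"Daidzein",0.491,0.431,-0.060,train
"3-Methyl galangin",0.477,0.552,0.075,train
"5-Hydroxyflavone",0.398,0.389,-0.009,test
"3,6,4'-Trihydroxyflavone",0.462,0.484,0.022,test
"3,4'-Dihydroxyflavone",0.462,0.447,-0.015,test
"(+/-)-Naringenin",0.462,0.484,0.022,test
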