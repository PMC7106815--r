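flavonoid,observed,predicted,residual,split
"5,7,2'-Trihydroxyflavone",2.013,2.003,-0.010,train
"Naringin",2.038,2.042,0.004,train
"(+/-)-Taxifolin",2.047,2.026,-0.021,train
"Quercetin",1.880,2.023,0.143,train
"Apigenin",2.040,1.999,-0.041,train
"Luteolin",2.055,2.012,-0.043,train
"Rutin",2.070,2.091,0.021,train
"Kaempferol",2.008,2.010,0.002,train
"Genistein",2.124,2.000,-0.124,train
"Baicalein",1.999,2.003,0.004,train
"Chrysin",1.850,1.987,0.137,train
"Resokaempferol",2.042,2.002,-0.040,train
"Galangin",1.950,1.997,0.047,train
"Isorhamnetin",1.950,2.023,0.073,train
"Morin",2.199,2.026,-0.173,train
"Myricetin",2.057,2.015,-0.042,train
"Scutellarein",1.995,2.029,0.034,train
"Tamarixetin",2.042,1.991,-0.051,train
"Daidzein",1.915,1.995,0.080,train
"3-Methyl galangin",1.932,1.976,0.044,train
"5-Hydroxyflavone",2.057,2.008,-0.049,test
"3,6,4'-Trihydroxyflavone",1.995,1.994,-0.001,test
"3,4'-Dihydroxyflavone",1.993,2.007,0.014,test
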