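subclass,flavonoid,oh_positions,och3_positions,other_substituents
Flavonol,"Myricetin","3, 5, 7, 3', 4', 5'",,
Flavonol,"Quercetin","3, 5, 7, 3', 4'",,
Flavonol,"Genistein","5, 7, 4'",,
Flavonol,"Isorhamnetin","3, 5, 7, 4'","3'",
Flavone,"Luteolin","5, 7, 3', 4'",,
Flavone,"Apigenin","5, 7, 4'",,
Flavone,"Chrysin","5, 7",,
Flavonol,"Kaempferol","3, 5, 7, 4'",,
Flavonol,"Tamarixetin","3, 5, 7, 3'","4'",
Flavonol,"Rutin","5, 7, 3', 4'",,O-Rutinose
Flavanone,"(+/-)-Taxifolin","3, 5, 7, 3', 4'",,
Flavonol,"3,6,4'-Trihydroxyflavone","3, 6, 4'",,
Flavone,"5,7,2'-Trihydroxyflavone","5, 7, 2'",,
Flavone,"Scutellarein","5, 6, 7, 4'",,
Flavanone,"Naringin","5, 4'",,O-beta-Neo-hesperidose
Flavone,"5-Hydroxyflavone","5",,
Flavonol,"3,4'-Dihydroxyflavone","3, 4'",,
Isoflavone,"Daidzein","7, 4'",,
Flavonol,"Morin","3, 5, 7, 2', 4'",,
Flavanone,"(+/-)-Naringenin","5, 7, 4'",,
Flavonol,"Resokaempferol","3, 7, 4'",,
Flavone,"Baicalein","5, 6, 7",,
Flavonol,"3-Methyl galangin","5, 7","3",
Flavonol,"Galangin","3, 5, 7",,
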