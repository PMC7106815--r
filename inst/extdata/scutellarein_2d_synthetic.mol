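scutellarein (synthetic 2D coordinates, generated from SMILES with Open Babel)
 OpenBabel09292605452D

 21 23  0  0  0  0  0  0  0  0999 V2000
   -0.8660   -1.5000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7321   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7321    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.5981    1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.4641    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -4.3301    1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -4.3301    2.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -5.1962    3.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -3.4641    3.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.5981    2.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660    1.5000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8660    1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.7321    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.5981    1.5000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
    1.7321    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.5981   -0.5000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.8660   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8660   -1.5000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  2  0  0  0  0
  2 21  1  0  0  0  0
  2  3  1  0  0  0  0
  3  4  2  0  0  0  0
  4  5  1  0  0  0  0
  4 12  1  0  0  0  0
  5 11  2  0  0  0  0
  5  6  1  0  0  0  0
  6  7  2  0  0  0  0
  7  8  1  0  0  0  0
  8  9  1  0  0  0  0
  8 10  2  0  0  0  0
 10 11  1  0  0  0  0
 12 13  1  0  0  0  0
 13 21  2  0  0  0  0
 13 14  1  0  0  0  0
 14 15  2  0  0  0  0
 15 16  1  0  0  0  0
 15 17  1  0  0  0  0
 17 18  1  0  0  0  0
 17 19  2  0  0  0  0
 19 20  1  0  0  0  0
 19 21  1  0  0  0  0
M  END
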