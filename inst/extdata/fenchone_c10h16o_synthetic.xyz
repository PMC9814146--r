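27
fenchone C10H16O; computed conformer (ETKDG + MMFF94), not an experimental geometry; centroid at origin
C     -2.123126    -0.627138     0.959520
C     -1.232055     0.108367    -0.039201
C     -2.081246     1.027861    -0.921240
C     -0.298838    -0.824284    -0.882113
C      0.463656    -1.837557     0.001703
C      1.445975    -0.951503     0.794797
C      1.225751     0.439734     0.175640
C      2.346956     1.429139     0.364273
C      0.863670     0.103263    -1.273457
C     -0.141389     0.907480     0.671337
O     -0.334400     1.765009     1.520286
H     -2.712257    -1.404094     0.461218
H     -1.549379    -1.090313     1.768806
H     -2.821675     0.064782     1.444593
H     -2.754530     0.443382    -1.557450
H     -1.477076     1.669862    -1.569227
H     -2.694305     1.699512    -0.308928
H     -0.805327    -1.296004    -1.728075
H      1.027665    -2.535736    -0.629182
H     -0.179737    -2.437431     0.649682
H      2.472776    -1.306580     0.653257
H      1.218204    -0.970193     1.866314
H      3.274178     1.068749    -0.093018
H      2.100401     2.396055    -0.087696
H      2.539514     1.605276     1.428049
H      0.559441     0.971796    -1.864542
H      1.667157    -0.419435    -1.805344
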