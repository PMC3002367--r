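# Toy 4-residue similarity matrix in NCBI text format (synthetic fixture,
# for parser tests only)
   A  G  V  Q
A  4 -1 -2  0
G -1  6 -3 -2
V -2 -3  5 -2
Q  0 -2 -2  6
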