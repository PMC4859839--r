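label,motif,distance
ILE117,N-H...O,2.03
ALY16B,O...H-O,1.93
ASN248,N-H...O,2.06
SER270,O-H...N,2.13
LEU249,N-H...O,1.94
THR37,O-H...N,1.82
ALA33,N-H...O,2.01
SER225,N-H...O,2.07
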