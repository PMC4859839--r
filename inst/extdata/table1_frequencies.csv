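bond_id,1.625,1.875,2.125,2.375,2.625,2.875,3.125,3.375
ILE117,0.5,15.0,32.7,27.2,14.4,7.2,2.1,0.7
ASP118_O1,9.1,35.2,6.3,0.6,1.3,3.0,5.5,7.8
ASP118_O2,9.0,32.8,5.7,1.2,2.8,8.1,12.1,12.7
ALY16B,13.6,19.6,6.2,1.7,1.7,1.5,1.3,1.4
ASN248,0.4,24.8,37.5,17.3,6.2,3.0,2.0,1.5
SER270,0.2,9.9,18.6,16.8,17.2,18.2,12.0,3.9
LEU249,0.1,11.8,34.2,26.6,13.4,7.5,2.8,1.7
THR37,1.0,17.3,16.0,6.1,2.7,3.1,3.4,3.4
ALA33,0.8,25.7,34.4,15.2,5.2,1.5,0.5,0.4
SER225,0.0,0.0,0.0,0.7,5.2,17.1,26.5,22.7
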