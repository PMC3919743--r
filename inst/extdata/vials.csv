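c_i,c_au,hu40,hu80
0,0,0,0
1,0,28.7,42.6
0,1,88.5,58.8
2,3,322.9,261.6
5,1,232,271.8
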