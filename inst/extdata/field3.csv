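net_id,brand,months_in_use,N1,N2,N3,N4
net01,B01,24,2,1,0,0
net02,B02,24,0,0,0,0
net03,B03,24,0,0,1,1
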