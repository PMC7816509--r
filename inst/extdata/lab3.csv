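net_id,brand,bursting_kpa,snag_n,abrasion_rubs,end_hole_mm,secondary_damage
net01,B01,350,100,200,3,none
net02,B02,700,200,400,3,none
net03,B03,250,59,410,10,laddering
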