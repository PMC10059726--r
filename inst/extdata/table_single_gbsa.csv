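"id","gaff_tip3p","se_gaff_tip3p","gaff_spce","se_gaff_spce","gaff2_tip3p","se_gaff2_tip3p","gaff2_spce","se_gaff2_spce"
"G1",-21.3,0.2,-18,0.1,-17.7,0.2,-16.8,0.2
"G2",-15.8,0.2,-16.1,0.1,-18.8,0.2,-19,0.2
"G3",-28.6,0.1,-27.7,0.2,-25.7,0.2,-24.1,0.2
"G4",-13.7,0.2,-12.9,0.2,-10.8,0.2,-7.2,0.2
"G5",-19,0.1,-20.7,0.1,-24.2,0.2,-24.5,0.2
"G6",-27.5,0.1,-24.3,0.1,-22,0.2,-20.2,0.2
"G7",-25,0.1,-22.2,0.2,-20.5,0.2,-18.4,0.2
"G8",4.6,0.2,7.3,0.2,-0.9,0.2,-1.7,0.2
"G9",-40.5,0.2,-39.7,0.1,-40.1,0.1,-36.7,0.1
"G10",-9.3,0.2,-9.4,0.2,-13.1,0.2,-13.1,0.2
"G11",-23,0.2,-19.9,0.2,-17.6,0.2,-15.8,0.2
"G12",-14.1,0.1,-14.6,0.1,-17,0.2,-17.1,0.2
"G13",-9.6,0.2,-11.8,0.1,-9.5,0.2,-11.3,0.2
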