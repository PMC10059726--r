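"id","gaff_tip3p","se_gaff_tip3p","gaff_spce","se_gaff_spce","gaff2_tip3p","se_gaff2_tip3p","gaff2_spce","se_gaff2_spce"
"G1",-22.5,0.2,-23.2,0.1,-22.7,0.2,-21.1,0.2
"G2",-14.1,0.2,-14.2,0.1,-18.1,0.2,-18.2,0.2
"G3",-33.7,0.1,-32.4,0.2,-30.6,0.2,-28.7,0.2
"G4",-22.8,0.2,-21.3,0.2,-18.2,0.2,-12,0.2
"G5",-18.3,0.1,-19.7,0.1,-24,0.2,-24.1,0.2
"G6",-32.5,0.2,-26.3,0.1,-25.7,0.2,-23.4,0.2
"G7",-27.7,0.1,-25.9,0.2,-23.1,0.2,-21,0.2
"G8",5.9,0.2,9.2,0.2,-2.4,0.2,-3.7,0.2
"G9",-33.9,0.2,-33.6,0.1,-33.5,0.1,-30.1,0.1
"G10",-6.6,0.2,-6.4,0.2,-11.8,0.2,-12,0.2
"G11",-28.7,0.2,-23.7,0.2,-21.8,0.2,-18.8,0.2
"G12",-15.2,0.1,-15.5,0.1,-19,0.2,-18.8,0.2
"G13",-3.3,0.2,-5.1,0.1,-3.6,0.2,-5,0.2
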