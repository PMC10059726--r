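"id","gaff_tip3p","se_gaff_tip3p","gaff_spce","se_gaff_spce","gaff2_tip3p","se_gaff2_tip3p","gaff2_spce","se_gaff2_spce"
"G1",4,0.3,-32.2,0.2,-82.8,0.3,-53.2,0.3
"G2",-2.9,0.2,-35.4,0.2,-89.6,0.3,-64.1,0.3
"G3",-3.5,0.2,-35.4,0.2,-82,0.3,-56.3,0.3
"G4",11.4,0.2,-20.2,0.2,-68.2,0.3,-45,0.3
"G5",6.7,0.2,-31.7,0.2,-88.4,0.3,-62.8,0.2
"G6",-2.3,0.2,-29.2,0.2,-83.3,0.3,-56.5,0.3
"G7",0.5,0.2,-32.1,0.3,-78.9,0.3,-51.4,0.3
"G8",15.1,0.3,-13.4,0.3,-69.9,0.3,-45.6,0.3
"G9",-22.5,0.2,-55,0.2,-98.3,0.3,-69.6,0.2
"G10",2.8,0.3,-28.7,0.3,-83.1,0.3,-57.6,0.3
"G11",6.7,0.3,-23.7,0.3,-74,0.3,-48.5,0.3
"G12",-4.9,0.2,-37.7,0.2,-89.9,0.3,-64.2,0.2
"G13",-0.5,0.3,-33,0.2,-78.5,0.3,-53.8,0.2
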