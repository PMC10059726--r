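"id","gaff_tip3p","se_gaff_tip3p","gaff_spce","se_gaff_spce","gaff2_tip3p","se_gaff2_tip3p","gaff2_spce","se_gaff2_spce"
"G1",-43.7,0.4,-181.3,0.5,-293.9,1.1,-131.3,0.5
"G2",-54.9,0.4,-178.7,0.5,-295.8,1.1,-140.3,0.5
"G3",-44.6,0.4,-169.4,0.5,-281.7,1.1,-127.3,0.5
"G4",-37.4,0.4,-159.6,0.5,-272,1.1,-122.6,0.5
"G5",-38.9,0.4,-174,0.5,-293.2,1.1,-137.9,0.5
"G6",-47.7,0.4,-159.6,0.5,-287.8,1.1,-131.7,0.5
"G7",-36,0.4,-167.4,0.5,-276.8,1.1,-122.3,0.6
"G8",-36.8,0.4,-155,0.5,-279,1.1,-126.2,0.5
"G9",-59.6,0.4,-183.9,0.5,-289.7,1.1,-131.2,0.5
"G10",-47.5,0.4,-170,0.5,-288.9,1.1,-134.3,0.6
"G11",-31.7,0.4,-155.2,0.5,-272.7,1.1,-119.5,0.6
"G12",-59.6,0.4,-183.8,0.5,-298.2,1.1,-142.8,0.5
"G13",-45.8,0.4,-169.1,0.5,-279.6,1.1,-125.5,0.5
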