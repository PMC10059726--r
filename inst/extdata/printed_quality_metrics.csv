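"table","column","rmse","mse","tau","pi"
"single_pb","gaff_tip3p",17.2,11.8,-0.1,-0.1
"single_pb","gaff_spce",16,10.6,-0.1,-0.1
"single_pb","gaff2_tip3p",15.1,11.9,-0.1,-0.1
"single_pb","gaff2_spce",13.3,10.5,-0.1,-0.1
"single_gb","gaff_tip3p",15.6,10.9,-0.1,-0.1
"single_gb","gaff_spce",14.7,10,-0.1,0
"single_gb","gaff2_tip3p",14.1,10.6,-0.1,-0.1
"single_gb","gaff2_spce",12.9,9.6,0,0
"three_pb","gaff_tip3p",38,37.2,0.5,0.6
"three_pb","gaff_spce",162.3,162,0.3,0.4
"three_pb","gaff2_tip3p",277.7,277.6,0.3,0.4
"three_pb","gaff2_spce",122.6,122.5,0.4,0.5
"three_gb","gaff_tip3p",12.1,-8.5,0.5,0.4
"three_gb","gaff_spce",25.3,23.6,0.3,0.3
"three_gb","gaff2_tip3p",74.7,74.3,0.3,0.3
"three_gb","gaff2_spce",48.8,48.3,0.4,0.3
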