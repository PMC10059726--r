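"id","dg_exp_kcal"
"G1",-6.53
"G2",-10.59
"G3",-8.03
"G4",-6.5
"G5",-5.46
"G6",-8.08
"G7",-7.07
"G8",-6.04
"G9",-6.32
"G10",-9.96
"G11",-6.26
"G12",-11.02
"G13",-8.58
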