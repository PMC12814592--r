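group,animal,organ,n_particles,mass_ng_per_100um3
MG,266,lung,6073,0.24
MG,279,lung,9131,0.31
MG,281,lung,12261,0.72
MG,266,LN,17012,0.66
MG,279,LN,14194,0.74
MG,281,LN,1702,0.04
PEG1,31,lung,10258,0.40
PEG1,32,lung,1701,0.12
PEG1,31,LN,14,0.01
PEG1,32,LN,3445,0.14
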