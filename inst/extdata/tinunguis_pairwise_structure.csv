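pop1,pop2,phist_dloop,fst_microsat
Colombian Amazon,Peruvian Amazon,0.108,0.129
Colombian Amazon,Ucayali,0.12,0.113
Colombian Amazon,Maranon,0.11,0.127
Colombian Amazon,Napo,0.226,0.074
Peruvian Amazon,Ucayali,-0.031,0
Peruvian Amazon,Maranon,-0.031,0.01925
Peruvian Amazon,Napo,0.009,0.046
Ucayali,Maranon,0.064,0.022
Ucayali,Napo,0.139,0.021
Maranon,Napo,0.163,0.016
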