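state C1a 0
state C1b 0
state C2 0
state O1 1
state O2 1
state C3 0
state C4 0
edge C1a C1b 9000 atp
edge C1b C1a 5
edge C1b C2 7.7
edge C2 C1b 5.8
edge C2 O1 4.9
edge O1 C2 10
edge O1 O2 7.1
edge O2 C3 3
edge C3 O2 7
edge C3 C4 6
edge C4 C3 12.8
edge C4 C1a 1.7
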