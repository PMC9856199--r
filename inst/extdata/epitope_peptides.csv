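label,sequence,start,saps
1 (wt),ENREVGDWRKNIDAL,184,
2 (R186Q),ENQEVGDWRKNIDAL,184,R186Q
3 (R192H),ENREVGDWHKNIDAL,184,R192H
4 (R192L),ENREVGDWLKNIDAL,184,R192L
5 (R192C),ENREVGDWCKNIDAL,184,R192C
6 (D190G),ENREVGGWRKNIDAL,184,D190G
7 (R192P),ENREVGDWPKNIDAL,184,R192P
8 (R192P K193E),ENREVGDWPENIDAL,184,R192P+K193E
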