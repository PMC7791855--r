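arm,round,possible_n,in_n
5pt,1,53,41
9pt,1,53,29
5pt,2,68,37
9pt,2,68,20
5pt,3,37,24
9pt,3,20,11
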