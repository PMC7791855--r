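arm,question,category,n
5pt,ease_of_use,easy_very_easy,45
5pt,ease_of_use,other,25
9pt,ease_of_use,easy_very_easy,33
9pt,ease_of_use,other,31
5pt,clarity,clear_very_clear,61
5pt,clarity,other,9
9pt,clarity,clear_very_clear,47
9pt,clarity,other,17
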