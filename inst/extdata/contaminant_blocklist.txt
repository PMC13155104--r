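# Common reagent/lab contaminant genera for 16S amplicon data.
# One name per line; matched case-insensitively at any rank.
Ralstonia
Variovorax
Streptococcus
Burkholderia
Cutibacterium
Corynebacterium
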