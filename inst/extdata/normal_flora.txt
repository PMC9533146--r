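# Default normal-flora genus list (editable; compiled from the oral
# microbiology literature on healthy salivary communities). One genus per
# line; case-insensitive. Report results with the list source used.
Streptococcus
Veillonella
Neisseria
Gemella
Granulicatella
Rothia
Haemophilus
Corynebacterium
Actinomyces
Staphylococcus
Abiotrophia
Lautropia
Kingella
Bergeyella
Alloprevotella
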