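# Default oral-disease-associated genus list (editable; compiled from the
# caries/periodontitis literature). One genus per line; case-insensitive.
Prevotella
Porphyromonas
Treponema
Fusobacterium
Tannerella
Selenomonas
Lactobacillus
Peptostreptococcus
Atopobium
Mogibacterium
Campylobacter
Leptotrichia
Olsenella
Scardovia
Parvimonas
Dialister
Filifactor
Aggregatibacter
Stomatobaculum
Oribacterium
Solobacterium
Sharpea
Lawsonella
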