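genus	oxygen_class
Streptococcus	facultative
Veillonella	anaerobic
Neisseria	aerobic
Rothia	facultative
Actinomyces	facultative
Prevotella	anaerobic
Porphyromonas	anaerobic
Treponema	anaerobic
Fusobacterium	anaerobic
Selenomonas	anaerobic
Lactobacillus	facultative
Peptostreptococcus	anaerobic
Atopobium	anaerobic
Mogibacterium	anaerobic
Campylobacter	facultative
Leptotrichia	anaerobic
Corynebacterium	aerobic
Haemophilus	facultative
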