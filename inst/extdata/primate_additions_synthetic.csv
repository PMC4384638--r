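species,cd33rsiglec_count
Saimiri_boliviensis,5
Tarsius_syrichta,5
Otolemur_garnettii,4
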