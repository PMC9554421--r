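eaa,requirement_mg_per_kg
histidine,10
isoleucine,20
leucine,39
lysine,30
threonine,15
tryptophan,4
valine,26
met_cys,15
phe_tyr,25
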