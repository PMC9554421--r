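source,histidine,isoleucine,leucine,lysine,threonine,tryptophan,valine,met_cys,phe_tyr
cereals,24,43,82,36,34,13,58,42,95
legumes,28,47,78,64,39,13,49,26,90
eggs,24,54,86,70,47,17,66,57,93
dairy,27,47,95,78,44,14,64,33,102
beef,34,48,81,89,46,12,50,40,80
pork,39,49,80,87,45,13,54,39,79
poultry,30,53,75,85,42,12,50,40,76
fish,29,46,81,92,44,11,52,40,76
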