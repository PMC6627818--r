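origin,location,arm,n,mean_mass_g,min_mass_g,max_mass_g
VA,"Corrotoman River, Virginia",cold,10,192,140,252
SC,"Charleston, South Carolina",cold,11,467,235,838
VA,"Corrotoman River, Virginia",heat,10,238,122,439
SC,"Charleston, South Carolina",heat,5,454,368,508
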