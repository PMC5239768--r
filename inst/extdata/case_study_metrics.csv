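metric,primary_mean,interior_mean,edge_mean,combined_mean
species_richness,18.5,15.8,10.7,13.9
abundance,147.7,129.3,48.6,122.0
biomass_g,24.7,14.1,3.4,14.7
abund_large_diurnal_tunneller,9.6,13.0,0.9,6.2
abund_large_nocturnal_tunneller,8.5,11.3,3.1,11.9
abund_small_diurnal_tunneller,43.5,55.6,12.7,51.7
abund_small_nocturnal_tunneller,17.5,6.4,4.4,10.6
abund_large_diurnal_roller,26.8,20.4,4.3,19.0
abund_large_nocturnal_roller,5.4,1.5,0.6,1.4
abund_small_diurnal_roller,33.7,21.0,22.6,21.1
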