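feature	relevance
freq_basic	31.40
redox_potential	12.73
isoelectric_point	7.80
freq_hbond	4.74
instability_index	4.62
charge_at_pH7.4	4.46
freq_all_basic	4.25
rna_ligation	4.16
freq_nonpolar	3.93
turn_propensity	3.30
helix_propensity	3.12
freq_ring	2.99
freq_aromatic	2.10
hydropathy_index	1.86
sheet_propensity	1.81
hydrophobicity_index	1.81
freq_all_helix_breaker	1.80
freq_strong_helix_breaker	1.11
freq_acidic	1.03
freq_hydroxyl	0.98
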