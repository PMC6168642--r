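type,percentage_of_length,diameter_um,spine_density,excitatory_per_um,inhibitory_per_um
proximal_basal,0.033,0.7,0.64,0.64,0.61
distal_basal,0.33,0.3,3.08,3.08,0.11
proximal_trunk,0.01,2.1,0.03,0.03,1.69
medial_trunk,0.01,2.0,2.37,2.37,0.54
distal_trunk,0.027,1.2,6.98,6.98,0.15
trunk_branches,0.355,0.5,3.52,3.52,0.11
prolonged_trunk,0.025,1.1,1.72,1.72,0.28
medial_tuft,0.053,0.6,0.6,0.69,0.12
distal_tuft,0.157,0.2,0.37,0.48,0.10
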