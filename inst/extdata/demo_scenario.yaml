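# Demo scenario: a small synthetic tolerance screen with ground truth.
# All generator parameters and the global seed are fixed here so a run is
# fully reproducible; see ?screen_config for the meaning of each field.
n_genes: 300
genome_length: 600000
mean_gene_length: 1000
n_go_terms: 40
n_clones: 2000
insert_range: [2000, 3000]
n_positive: 12
n_negative: 0
s_positive: 2.0
s_negative: -1.0
noise_sd: 0.1
dye_bias: true
probes_per_gene: 1
alpha_cgh: 0.05
cgh_correction: none
cast_threshold: 0.8
go_correction: BH
kinetics_true_iie: 49.1
kinetics_noise_sd: 0.005
alpha_kinetics: 0.05
max_kinetics_genes: 20
seed: 1
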