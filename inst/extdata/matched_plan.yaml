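# Matched serum / normal-skin / primary-tumour / metastasis quadruples on
# the custom panel, with planted compartment categories.
seed: 20260104
n_healthy: 0
n_circadian_donors: 0
n_individuals: 6
n_tissue_exclusive: 15
n_serum_exclusive: 2
n_serum_higher: 12
n_gradient: 5
serum_higher_delta_cq: -2.5
gradient_step_cq: -1.5
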