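# Healthy serum cohort on the whole-miRNome panel: 19 single-draw donors
# plus 4 circadian donors sampled at morning/midday/evening.
seed: 20260101
n_healthy: 19
n_circadian_donors: 4
frac_absent: 0.63
n_high: 82
n_unstable: 30
n_circadian: 7
noise_sd: 0.3
unstable_sd: 1.3
circadian_delta_cq: -1.9
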