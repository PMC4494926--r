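# 131-sample serum QC stream (custom panel) with 31 planted failures:
# 11 hemolytic, 10 blood-cell contaminated, 10 with poor spike recovery.
seed: 20260102
n_healthy: 131
n_circadian_donors: 0
frac_absent: 0.2
n_high: 30
n_unstable: 0
n_circadian: 0
n_hemolytic: 11
n_contaminated: 10
n_poor_spike: 10
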