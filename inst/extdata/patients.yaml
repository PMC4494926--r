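# Patient cohort on the custom panel: 30 healthy donors plus melanoma
# patients of stages 0/I/II/III/IV (4/11/17/11/9); late-stage differential
# effects are attached programmatically (default_stage_effects).
seed: 20260103
n_healthy: 30
n_circadian_donors: 0
stage_n:
  "0": 4
  "I": 11
  "II": 17
  "III": 11
  "IV": 9
frac_absent: 0.0
n_high: 60
n_unstable: 0
n_circadian: 0
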