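speed_mean: 3.2
speed_sd: 1.112625
heading_noise_kappa: 5.76
goal_weight_base: 0.132
belief_error_sd: 18.72
learning_rate: 0.87
search_dwell_s: 2.99952
dwell_mult3: 5.98
lapse_rate: 0.373913
lapse_sd_mult: 0.4202088
lapse_recover_s: 39.2608696
goal_impair: 0.86
belief_impair: 0.8
noise_impair: 0.275
learning_impair: 1.8
stage_goal_mult1: 4.4784
stage_goal_mult2: 1.2
stage_goal_mult3: 1.0
stage_belief_mult1: 0.14472
stage_belief_mult2: 0.78
stage_belief_mult3: 1.2
hc_impairment_mean: 0.171925
hc_impairment_sd: 0.3
amci_impairment_mean: 2.5
amci_impairment_sd: 0.62
trait_sd: 0.552
stage_trait_sd: 1.5
radial_bias_sd: 1.0
cognitive_coupling: 1.7
cognitive_link:
  HC:
    age:
    - 73.0
    - 6.7
    sex_f: 0.75
    education:
    - 12.4
    - 3.13
    moca:
    - 28.0
    - 1.79
    moca_mis:
    - 14.1
    - 0.89
    ad8:
    - 0.6
    - 1.34
    cdr: 0.0
    cdr_sob:
    - 0.05
    - 0.134
  aMCI:
    age:
    - 76.1
    - 7.2
    sex_f: 0.5
    education:
    - 12.4
    - 3.39
    moca:
    - 21.1
    - 2.55
    moca_mis:
    - 7.2
    - 3.39
    ad8:
    - 4.7
    - 1.7
    cdr: 0.5
    cdr_sob:
    - 2.11
    - 1.23
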