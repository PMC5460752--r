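# Demonstration analysis: two East Asian case-control studies of
# Val279Phe and one European cohort study carrying the four rare
# loss-of-function variants plus Val379Ala, simulated under the null.
seed: 1
tau: 0
reference:
  percent: 65
  sd: 2.26
trial:
  id: darapladib
  rr: 0.95
  ci_lo: 0.89
  ci_hi: 1.02
power:
  target_rr: 0.8
  alpha: 0.05
studies:
  - study_id: EAS_cc_1
    ancestry: EAS
    n_case: 3000
    n_ctrl: 3000
    noise_sd: 0.171
    variants: [Val279Phe]
  - study_id: EAS_cc_2
    ancestry: EAS
    n_case: 3000
    n_ctrl: 3000
    noise_sd: 0.171
    variants: [Val279Phe]
  - study_id: EUR_cohort
    ancestry: EUR
    n_individuals: 40000
    noise_sd: 0.283
    variants: ["c.109+2T>C", Arg82His, Val279Phe, Gln287Ter, Val379Ala]
    activity_model_override:
      "c.109+2T>C": [1, 0.36, 0.13]
      Arg82His: [1, 0.36, 0.13]
      Val279Phe: [1, 0.36, 0.13]
      Gln287Ter: [1, 0.36, 0.13]
instruments:
  - id: Val279Phe
    type: per_allele
    variant: Val279Phe
    ancestries: [EAS]
  - id: Val379Ala
    type: per_allele
    variant: Val379Ala
  - id: lof_burden
    type: per_carrier
    lof: ["c.109+2T>C", Arg82His, Val279Phe, Gln287Ter]
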